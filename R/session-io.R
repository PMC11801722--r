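#' Write a session to a directory of plain-text files
#'
#' Serialises a session as `trials.csv` (one row per trial), `spikes.csv`
#' (`unit_id`, `trial_id`, `spike_time_ms`), `eye.csv` (`trial_id`, `t_ms`,
#' `x_deg`, `y_deg`) and `session.json` (layout, seed, behavioural config).
#' All times are ms relative to array onset; positions are 0-based.
#' Serialisation is deterministic, so identical seed and configuration yield
#' byte-identical files.
#'
#' @param session a `search_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  if (!inherits(session, "search_session")) stop("not a search_session")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(session$trials, file.path(dir, "trials.csv"), row.names = FALSE)

  sp <- do.call(rbind, lapply(seq_along(session$spikes), function(ui) {
    tr <- session$spikes[[ui]]
    n <- vapply(tr, length, integer(1))
    data.frame(unit_id = names(session$spikes)[ui],
               trial_id = rep(seq_along(tr), n),
               spike_time_ms = unlist(tr, use.names = FALSE))
  }))
  write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)

  ey <- do.call(rbind, lapply(seq_along(session$eye), function(i)
    cbind(trial_id = i, session$eye[[i]])))
  write.csv(ey, file.path(dir, "eye.csv"), row.names = FALSE)

  meta <- list(
    layout = unclass(session$layout),
    window = session$window,
    behavior = session$behavior,
    rng_seed = session$rng_seed,
    unit_ids = session$unit_ids
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "session.json"))
  invisible(dir)
}

#' Read a session from a directory written by [write_session()]
#'
#' The planted generator ground truth (archetypes, bases) is not part of the
#' on-disk format; the returned session carries `population = NULL`.
#'
#' @param dir session directory.
#' @return a `search_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "session.json"))
  trials <- read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  sp <- read.csv(file.path(dir, "spikes.csv"), stringsAsFactors = FALSE)
  ey <- read.csv(file.path(dir, "eye.csv"), stringsAsFactors = FALSE)

  unit_ids <- meta$unit_ids
  spikes <- lapply(unit_ids, function(uid) {
    rows <- sp[sp$unit_id == uid, ]
    lapply(seq_len(nrow(trials)), function(i)
      rows$spike_time_ms[rows$trial_id == i])
  })
  names(spikes) <- unit_ids
  eye <- lapply(seq_len(nrow(trials)), function(i) {
    e <- ey[ey$trial_id == i, c("t_ms", "x_deg", "y_deg")]
    rownames(e) <- NULL
    e
  })
  layout <- structure(meta$layout, class = "task_layout")
  structure(list(
    unit_ids = unit_ids,
    trials = trials,
    spikes = spikes,
    eye = eye,
    layout = layout,
    population = NULL,
    window = meta$window,
    behavior = meta$behavior,
    rng_seed = meta$rng_seed
  ), class = "search_session")
}
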