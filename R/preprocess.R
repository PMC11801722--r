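#' Gaussian smoothing-kernel parameters
#'
#' @param sigma_ms kernel SD in ms (default 10).
#' @param truncation kernel support half-width in multiples of sigma.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(sigma_ms = 10, truncation = 4) {
  if (sigma_ms <= 0) stop("`sigma_ms` must be positive")
  structure(list(sigma_ms = sigma_ms, truncation = truncation),
            class = "kernel_params")
}

#' Detect saccades in an eye trace
#'
#' Computes instantaneous horizontal and vertical velocity by central
#' differences on the position samples, marks samples whose speed
#' `sqrt(vx^2 + vy^2)` exceeds `v_thresh`, merges suprathreshold runs
#' separated by gaps up to `merge_gap_ms`, and keeps events whose start-to-end
#' displacement is at least `amp_thresh` and whose duration is at least
#' `min_dur_ms`.
#'
#' @param eye data frame with `t_ms`, `x_deg`, `y_deg` (uniform sampling).
#' @param v_thresh velocity threshold, deg/s.
#' @param amp_thresh amplitude threshold, deg.
#' @param merge_gap_ms suprathreshold runs closer than this are merged.
#' @param min_dur_ms minimum event duration.
#' @return data frame with one row per saccade: `onset`, `offset` (ms),
#'   `amplitude` (deg), `direction_deg`.
#' @export
detect_saccades <- function(eye, v_thresh = 50, amp_thresh = 0.4,
                            merge_gap_ms = 10, min_dur_ms = 8) {
  if (nrow(eye) < 3) stop("eye trace must contain at least 3 samples")
  t <- eye$t_ms
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6) stop("eye trace must be uniformly sampled")
  h <- dt[1] / 1000                      # s per sample
  n <- nrow(eye)
  vx <- c(NA, (eye$x_deg[3:n] - eye$x_deg[1:(n - 2)]) / (2 * h), NA)
  vy <- c(NA, (eye$y_deg[3:n] - eye$y_deg[1:(n - 2)]) / (2 * h), NA)
  speed <- sqrt(vx^2 + vy^2)
  above <- !is.na(speed) & speed > v_thresh

  runs <- logical_runs(above)
  if (nrow(runs) == 0)
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      amplitude = numeric(0), direction_deg = numeric(0)))
  # merge runs separated by short gaps
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    gap_ms <- (runs$start[i] - merged$end[nrow(merged)] - 1) * dt[1]
    if (gap_ms <= merge_gap_ms) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else merged <- rbind(merged, runs[i, ])
  }

  out <- lapply(seq_len(nrow(merged)), function(i) {
    i0 <- max(merged$start[i] - 1L, 1L)    # flanking samples capture the
    i1 <- min(merged$end[i] + 1L, n)       # full displacement
    dx <- eye$x_deg[i1] - eye$x_deg[i0]
    dy <- eye$y_deg[i1] - eye$y_deg[i0]
    data.frame(onset = t[merged$start[i]], offset = t[merged$end[i]],
               amplitude = sqrt(dx^2 + dy^2),
               direction_deg = atan2(dy, dx) * 180 / pi,
               duration = (merged$end[i] - merged$start[i] + 1L) * dt[1])
  })
  out <- do.call(rbind, out)
  out <- out[out$amplitude >= amp_thresh & out$duration >= min_dur_ms, ]
  rownames(out) <- NULL
  out[, c("onset", "offset", "amplitude", "direction_deg")]
}

#' Spike-density function by Gaussian convolution
#'
#' `rate(t) = sum_spikes N(t - t_spike; sigma) * 1000` spikes/s, evaluated on
#' a uniform 1-ms grid; the kernel is truncated at `truncation * sigma` with
#' no edge renormalisation, so the time integral of the rate equals the spike
#' count up to truncation error.
#'
#' @param spike_times spike times in ms (may be empty).
#' @param grid uniform 1-ms time grid (left bin edges).
#' @param kernel a [kernel_params()].
#' @return numeric rate vector, spikes/s, aligned with `grid`.
#' @export
spike_density <- function(spike_times, grid, kernel = kernel_params()) {
  step <- grid[2] - grid[1]
  half <- ceiling(kernel$truncation * kernel$sigma_ms / step)
  # bin spikes on an extended grid so edge spikes contribute
  ext <- c(grid[1] - half * step + step * (0:(half - 1)),
           grid,
           grid[length(grid)] + step * (1:half))
  spike_times <- spike_times[spike_times >= ext[1] &
                               spike_times < ext[length(ext)] + step]
  counts <- tabulate(findInterval(spike_times, ext), nbins = length(ext))
  kern <- dnorm(seq(-half, half) * step, 0, kernel$sigma_ms) * 1000
  rate <- stats::filter(counts, kern, sides = 2)
  out <- as.numeric(rate[(half + 1):(half + length(grid))])
  out[is.na(out)] <- 0
  out
}

#' Smoothed rate matrix for one unit
#'
#' @param session a `search_session`.
#' @param unit_id unit identifier (name in `session$spikes`).
#' @param trial_ids trial ids (default: all trials).
#' @param window ms window `c(start, end)`, half-open, 1-ms grid.
#' @param kernel a [kernel_params()].
#' @return trials x time matrix of rates (spikes/s) with attribute `time`.
#' @export
rate_matrix <- function(session, unit_id, trial_ids = session$trials$trial_id,
                        window = c(-300, 500), kernel = kernel_params()) {
  grid <- seq(window[1], window[2] - 1L)
  sp <- session$spikes[[unit_id]]
  if (is.null(sp)) stop("unknown unit: ", unit_id)
  m <- t(vapply(trial_ids, function(i) spike_density(sp[[i]], grid, kernel),
                numeric(length(grid))))
  attr(m, "time") <- grid
  m
}

#' Normalise a unit's rates by its maximum condition-mean response
#'
#' Divides every rate by the maximum of the condition-mean spike-density
#' functions within the normalisation window (default 40-200 ms after array
#' onset). If no condition has a positive response in the window the unit is
#' flagged for exclusion. The operation is idempotent.
#'
#' @param rates named list of trials x time matrices (one per condition),
#'   each with a `time` attribute.
#' @param window ms normalisation window, half-open.
#' @return list with `rates` (normalised), `norm_factor`, `excluded`.
#' @export
normalize_unit <- function(rates, window = c(40, 200)) {
  stopifnot(is.list(rates), length(rates) >= 1)
  peak <- max(vapply(rates, function(m) {
    tt <- attr(m, "time")
    sel <- in_window(tt, window)
    if (!any(sel)) stop("normalisation window outside rate grid")
    max(colMeans(m[, sel, drop = FALSE]))
  }, numeric(1)))
  if (!is.finite(peak) || peak <= 0)
    return(list(rates = rates, norm_factor = NA_real_, excluded = TRUE))
  list(rates = lapply(rates, function(m) {
    out <- m / peak
    attr(out, "time") <- attr(m, "time")
    out
  }), norm_factor = peak, excluded = FALSE)
}

#' Screen a unit for a significant visual response
#'
#' Paired t-test across trials of the mean rate 40-120 ms after array onset
#' against the baseline -150-0 ms before onset.
#'
#' @param rates trials x time rate matrix with `time` attribute.
#' @param alpha significance level.
#' @param resp_window,base_window ms windows, half-open.
#' @return `TRUE` if the unit responds at the array onset.
#' @export
screen_visual_responsive <- function(rates, alpha = 0.05,
                                     resp_window = c(40, 120),
                                     base_window = c(-150, 0)) {
  if (nrow(rates) < 2) stop("need at least 2 trials to screen responsiveness")
  tt <- attr(rates, "time")
  resp <- rowMeans(rates[, in_window(tt, resp_window), drop = FALSE])
  base <- rowMeans(rates[, in_window(tt, base_window), drop = FALSE])
  d <- resp - base
  if (sd(d) == 0) return(FALSE)
  t.test(resp, base, paired = TRUE)$p.value < alpha
}

#' Named trial contrasts
#'
#' Pre-defined two-condition contrasts. `singleton_vs_nonsingleton_rf`
#' compares singleton-present trials with the singleton versus a non-salient
#' distractor in the RF; `singleton_vs_mixed` compares the singleton in the
#' RF against the identical stimulus in a mixed-colour (non-salient) display.
#'
#' @param name contrast name.
#' @return named list of per-condition filters.
#' @export
trial_contrast <- function(name = c("singleton_vs_nonsingleton_rf",
                                    "singleton_vs_mixed")) {
  name <- match.arg(name)
  switch(name,
    singleton_vs_nonsingleton_rf = list(
      singleton_in_rf = list(display_type = "singleton_present",
                             rf_content = "salient_distractor"),
      nonsingleton_in_rf = list(display_type = "singleton_present",
                                rf_content = "nonsalient_distractor")),
    singleton_vs_mixed = list(
      singleton_in_rf = list(display_type = "singleton_present",
                             rf_content = "salient_distractor"),
      matched_in_rf = list(display_type = "mixed_color",
                           rf_content = "salient_distractor")))
}

#' Select trials for a contrast
#'
#' Filters trials per condition by display type and RF content, keeping only
#' trials in which the first saccade was made away from the RF, and applies
#' the minimum-trials inclusion criterion (default 10 per condition).
#'
#' @param session a `search_session`.
#' @param contrast a [trial_contrast()] result or a named list of filters,
#'   each with optional elements `display_type` and `rf_content`.
#' @param saccade_away if `TRUE` keep only first saccades away from the RF.
#' @param min_trials minimum trials per condition for inclusion.
#' @return named list of trial-id vectors with attributes `included`
#'   (logical) and `n` (per-condition counts).
#' @export
select_trials <- function(session, contrast, saccade_away = TRUE,
                          min_trials = 10L) {
  if (is.character(contrast)) contrast <- trial_contrast(contrast)
  if (is.null(names(contrast))) stop("contrast conditions must be named")
  tr <- session$trials
  sets <- lapply(contrast, function(f) {
    bad <- setdiff(names(f), c("display_type", "rf_content"))
    if (length(bad)) stop("unknown condition filter field: ", bad[1])
    keep <- rep(TRUE, nrow(tr))
    if (!is.null(f$display_type)) {
      if (!f$display_type %in% tr$display_type &&
          !f$display_type %in% c("singleton_present", "singleton_absent", "mixed_color"))
        stop("unknown display type: ", f$display_type)
      keep <- keep & tr$display_type == f$display_type
    }
    if (!is.null(f$rf_content)) keep <- keep & tr$rf_content == f$rf_content
    if (saccade_away) keep <- keep & tr$first_saccade_dir == "away_from_rf"
    tr$trial_id[keep]
  })
  n <- vapply(sets, length, integer(1))
  attr(sets, "n") <- n
  attr(sets, "included") <- all(n >= min_trials)
  sets
}
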