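#' Behavioural summary of one or more sessions
#'
#' Computes first-saccade and overall saccade-to-singleton rates (with a
#' chi-squared test of the first-saccade rate against the 1/8 random-search
#' expectation), median search times and first-saccade latencies per display
#' type with Wilcoxon rank-sum comparisons between display types, and mean
#' saccade counts.
#'
#' @param sessions a `search_session` or list of them.
#' @return object of class `behavior_summary`.
#' @export
summarize_behavior <- function(sessions) {
  if (inherits(sessions, "search_session")) sessions <- list(sessions)
  tr <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  if (nrow(tr) == 0) stop("no completed trials")

  sing <- tr[!is.na(tr$singleton_pos) & tr$display_type == "singleton_present", ]
  first_to_singleton <- NA_real_; chisq <- NULL
  if (nrow(sing) > 0) {
    k <- sum(sing$first_saccade_pos == sing$singleton_pos)
    first_to_singleton <- k / nrow(sing)
    chisq <- suppressWarnings(
      chisq.test(c(k, nrow(sing) - k), p = c(1 / 8, 7 / 8)))
  }
  # saccade count: first saccade plus a corrective saccade when the first
  # saccade missed the target
  n_sacc <- 1 + (tr$first_saccade_pos != tr$target_pos)
  overall_to_singleton <- if (nrow(sing) > 0) {
    sum(sing$first_saccade_pos == sing$singleton_pos) /
      sum(n_sacc[!is.na(tr$singleton_pos) & tr$display_type == "singleton_present"])
  } else NA_real_

  displays <- unique(tr$display_type)
  med_st <- tapply(tr$search_time, tr$display_type, median)
  med_lat <- tapply(tr$first_saccade_latency, tr$display_type, median)
  mean_sacc <- tapply(n_sacc, tr$display_type, mean)

  comparisons <- NULL
  note <- NULL
  if (length(displays) >= 2) {
    pairs <- utils::combn(sort(displays), 2, simplify = FALSE)
    comparisons <- do.call(rbind, lapply(pairs, function(p) {
      w <- wilcox.test(tr$search_time[tr$display_type == p[1]],
                       tr$search_time[tr$display_type == p[2]])
      data.frame(display_a = p[1], display_b = p[2],
                 p_search_time = w$p.value)
    }))
  } else {
    note <- "single display type: cross-type comparisons skipped"
  }

  structure(list(
    n_trials = nrow(tr),
    first_saccade_to_singleton_rate = first_to_singleton,
    overall_saccades_to_singleton_rate = overall_to_singleton,
    chisq_vs_random = if (!is.null(chisq))
      list(statistic = unname(chisq$statistic), p = chisq$p.value,
           expected_rate = 1 / 8),
    median_search_time = med_st,
    median_first_saccade_latency = med_lat,
    mean_saccade_count = mean_sacc,
    display_comparisons = comparisons,
    note = note
  ), class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("behavior_summary over", x$n_trials, "trials\n")
  cat(sprintf("  first saccade to singleton: %.1f%% (random search: 12.5%%",
              100 * x$first_saccade_to_singleton_rate))
  if (!is.null(x$chisq_vs_random))
    cat(sprintf(", chi-squared p = %.3g", x$chisq_vs_random$p))
  cat(")\n  median search time (ms):\n")
  print(round(x$median_search_time, 1))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Median split of search times into fast and slow trials
#'
#' Labels each trial fast or slow by its search time relative to the median,
#' computed separately per display type by default. Trials tied at the
#' median are assigned alternately to whichever side is smaller, keeping the
#' imbalance at most 1.
#'
#' @param session a `search_session`.
#' @param per_display split within each display type (default) or pooled.
#' @return data frame with `trial_id`, `display_type`, `speed`
#'   (`"fast"`/`"slow"`).
#' @export
median_split <- function(session, per_display = TRUE) {
  tr <- session$trials
  split_one <- function(times, ids) {
    if (length(unique(times)) < 2)
      stop("search times are all equal: median split undefined")
    med <- median(times)
    speed <- ifelse(times < med, "fast", ifelse(times > med, "slow", NA))
    for (i in which(is.na(speed))) {
      nf <- sum(speed == "fast", na.rm = TRUE)
      ns <- sum(speed == "slow", na.rm = TRUE)
      speed[i] <- if (nf <= ns) "fast" else "slow"
    }
    data.frame(trial_id = ids, speed = speed)
  }
  groups <- if (per_display) split(seq_len(nrow(tr)), tr$display_type)
            else list(all = seq_len(nrow(tr)))
  out <- do.call(rbind, lapply(groups, function(idx)
    cbind(split_one(tr$search_time[idx], tr$trial_id[idx]),
          display_type = tr$display_type[idx])))
  rownames(out) <- NULL
  out[order(out$trial_id), c("trial_id", "display_type", "speed")]
}

#' Fast-versus-slow response contrast per unit
#'
#' For trials of a given RF condition (default: the singleton in the RF on
#' singleton-present displays, first saccade away from the RF), contrasts
#' each unit's window firing rate between fast and slow trials: modulation
#' index `(FR_fast - FR_slow) / (FR_fast + FR_slow)` and the fast-versus-slow
#' AUROC. Negative values mean weaker distractor responses on fast trials.
#'
#' @param session a `search_session`.
#' @param split a [median_split()] result.
#' @param rf_content RF condition filter.
#' @param display_type display filter.
#' @param window ms response window, half-open.
#' @param min_trials minimum fast and slow trials per unit.
#' @param kernel a [kernel_params()].
#' @return data frame with one row per unit: `unit_id`, `mi`, `auroc`,
#'   `n_fast`, `n_slow`, `included`.
#' @export
median_split_contrast <- function(session, split,
                                  rf_content = "salient_distractor",
                                  display_type = "singleton_present",
                                  window = c(150, 200),
                                  min_trials = 10L,
                                  kernel = kernel_params()) {
  tr <- session$trials
  keep <- tr$display_type == display_type & tr$rf_content == rf_content &
    tr$first_saccade_dir == "away_from_rf"
  ids <- tr$trial_id[keep]
  sp <- split$speed[match(ids, split$trial_id)]
  fast_ids <- ids[sp == "fast"]
  slow_ids <- ids[sp == "slow"]
  out <- lapply(session$unit_ids, function(uid) {
    ok <- length(fast_ids) >= min_trials && length(slow_ids) >= min_trials
    mi <- au <- NA_real_
    if (ok) {
      rf_rates <- rate_matrix(session, uid, c(fast_ids, slow_ids),
                              c(window[1], window[2]), kernel)
      wm <- rowMeans(rf_rates)
      f <- wm[seq_along(fast_ids)]
      s <- wm[-seq_along(fast_ids)]
      mi <- modulation_index(mean(f), mean(s))
      au <- auroc(f, s)
    }
    data.frame(unit_id = uid, mi = mi, auroc = au,
               n_fast = length(fast_ids), n_slow = length(slow_ids),
               included = ok)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
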