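#' Modulation index between two firing rates
#'
#' `(FR1 - FR2) / (FR1 + FR2)`, the normalised rate difference used to
#' quantify singleton suppression or enhancement per unit; rates are window
#' means (150-200 ms after array onset in the standard analyses). Undefined
#' (NA) when both rates are zero; such units are excluded from index
#' distributions.
#'
#' @param fr1,fr2 non-negative firing rates (vectorised).
#' @return index in \[-1, 1\], or NA where `fr1 + fr2 == 0`.
#' @export
modulation_index <- function(fr1, fr2) {
  if (any(fr1 < 0 | fr2 < 0, na.rm = TRUE)) stop("rates must be non-negative")
  s <- fr1 + fr2
  ifelse(s > 0, (fr1 - fr2) / s, NA_real_)
}

#' Effect size for rank tests
#'
#' `r = z / sqrt(n)` for Wilcoxon signed-rank and rank-sum z statistics,
#' where `n` is the number of observations.
#'
#' @param z rank-test z statistic.
#' @param n number of observations (>= 1).
#' @return effect size r.
#' @export
rank_effect_size <- function(z, n) {
  if (any(n < 1)) stop("`n` must be >= 1")
  z / sqrt(n)
}

#' AUROC by criterion sweep
#'
#' Area under the ROC curve comparing two sets of trial-wise spike counts.
#' The ROC curve is constructed by sweeping a spike-count criterion from
#' below zero to the maximum observed count and plotting, for each criterion,
#' the proportion of trials in each condition whose count exceeds it; the
#' area is computed by the trapezoid rule. Ties at the criterion contribute
#' one half, so the value equals the Mann-Whitney `U / (n1 * n2)`.
#'
#' @param a,b spike counts (or rates) for the two conditions.
#' @return AUROC in \[0, 1\]: values above 0.5 mean `a` tends to exceed `b`.
#' @export
auroc <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  crit <- c(min(c(a, b)) - 1, sort(unique(c(a, b))))
  hit <- vapply(crit, function(cc) mean(a > cc), numeric(1))
  fa <- vapply(crit, function(cc) mean(b > cc), numeric(1))
  # points run from (1, 1) down to (0, 0) as the criterion rises
  sum(-diff(fa) * (head(hit, -1) + tail(hit, -1)) / 2)
}

# rank-form AUROC, equal to auroc() (equality is exhaustively tested);
# used on permutation nulls where the sweep would be needlessly slow
auroc_rank <- function(a, b) {
  r <- rank(c(a, b))
  (sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2) /
    (length(a) * length(b))
}

#' Time-resolved AUROC with per-unit permutation null
#'
#' Computes the AUROC per time bin between two conditions' spike counts and
#' a null distribution obtained by shuffling trial indices between the
#' conditions (one label permutation per shuffle, applied across all bins).
#'
#' @param counts_a,counts_b trials x bins count matrices (>= 10 trials per
#'   condition in the standard analyses).
#' @param n_shuffles number of label shuffles for the null.
#' @param seed integer seed for the shuffles.
#' @return list with `auroc` (per-bin), `null` (n_shuffles x bins matrix),
#'   and `n_bins`.
#' @export
time_resolved_auroc <- function(counts_a, counts_b, n_shuffles = 500, seed = 1L) {
  stopifnot(ncol(counts_a) == ncol(counts_b))
  nb <- ncol(counts_a)
  na <- nrow(counts_a)
  pooled <- rbind(counts_a, counts_b)
  obs <- vapply(seq_len(nb), function(j) auroc(counts_a[, j], counts_b[, j]),
                numeric(1))
  null <- with_seed(child_seed(seed, 3L), {
    t(vapply(seq_len(n_shuffles), function(s) {
      idx <- sample(nrow(pooled))
      ia <- idx[seq_len(na)]
      ib <- idx[-seq_len(na)]
      vapply(seq_len(nb), function(j) auroc_rank(pooled[ia, j], pooled[ib, j]),
             numeric(1))
    }, numeric(nb)))
  })
  list(auroc = obs, null = null, n_bins = nb)
}

#' Population-level AUROC significance with FDR correction
#'
#' Tests, per time bin, whether the across-unit average AUROC differs from
#' its permutation expectation. The population null is built by drawing one
#' null AUROC per unit (from each unit's shuffle distribution) and averaging
#' across units, repeated `n_population_nulls` times; two-sided p-values are
#' corrected across time bins by the Benjamini-Hochberg procedure.
#'
#' @param aurocs units x bins matrix of observed AUROCs.
#' @param nulls units x bins x shuffles array of per-unit null AUROCs.
#' @param n_population_nulls number of population-level null averages.
#' @param q FDR level.
#' @param seed integer seed.
#' @return list with `mean_auroc`, `p` (per bin), `significant` (FDR mask),
#'   and `null_means` (n_population_nulls x bins).
#' @export
population_auroc_test <- function(aurocs, nulls, n_population_nulls = 1000,
                                  q = 0.05, seed = 1L) {
  if (length(dim(nulls)) != 3) stop("`nulls` must be a units x bins x shuffles array")
  n_units <- nrow(aurocs)
  nb <- ncol(aurocs)
  if (dim(nulls)[1] != n_units || dim(nulls)[2] != nb)
    stop("null array does not match the observed AUROC matrix")
  ns <- dim(nulls)[3]
  obs <- colMeans(aurocs)
  null_means <- with_seed(child_seed(seed, 4L), {
    draw <- matrix(sample.int(ns, n_population_nulls * n_units, replace = TRUE),
                   n_population_nulls, n_units)
    vapply(seq_len(nb), function(j) {
      nb_mat <- nulls[, j, , drop = TRUE]          # units x shuffles
      if (n_units == 1) nb_mat <- matrix(nb_mat, nrow = 1)
      vapply(seq_len(n_population_nulls), function(p)
        mean(nb_mat[cbind(seq_len(n_units), draw[p, ])]), numeric(1))
    }, numeric(n_population_nulls))
  })
  p <- vapply(seq_len(nb), function(j) perm_pvalue(obs[j], null_means[, j]),
              numeric(1))
  list(mean_auroc = obs, p = p,
       significant = p.adjust(p, "BH") < q,
       null_means = null_means)
}

#' Latency of a condition difference
#'
#' Latency is the left edge of the first 5-ms bin beginning a run of at
#' least `n_consec` consecutive significant bins, where per-bin significance
#' is a one-sample t test of the trial-wise condition differences against
#' zero with Bonferroni correction over the analysis bins.
#'
#' @param diffs trials x bins matrix of per-trial condition differences in
#'   5-ms bins, with a `time` attribute giving bin left edges (ms).
#' @param alpha familywise significance level before Bonferroni division.
#' @param n_consec required run length in bins.
#' @param from_ms earliest bin edge considered for the run.
#' @param family Bonferroni family size; defaults to the number of bins at or
#'   after `from_ms`.
#' @return list with `latency_ms` (or NA if no qualifying run), `p` and
#'   `significant` per bin.
#' @export
difference_latency <- function(diffs, alpha = 0.05, n_consec = 5L,
                               from_ms = 0, family = NULL) {
  tt <- attr(diffs, "time")
  if (is.null(tt)) stop("`diffs` must carry a `time` attribute")
  if (ncol(diffs) < n_consec) stop("fewer bins than the required run length")
  use <- tt >= from_ms
  if (is.null(family)) family <- sum(use)
  p <- apply(diffs, 2, function(x) {
    if (sd(x) == 0) return(1)
    t.test(x)$p.value
  })
  sig <- p < alpha / family & use
  runs <- logical_runs(sig)
  runs <- runs[runs$length >= n_consec, , drop = FALSE]
  latency <- if (nrow(runs) > 0) tt[runs$start[1]] else NA_real_
  list(latency_ms = latency, p = p, significant = sig)
}

#' Permutation comparison of group latencies
#'
#' Tests the difference between the median latencies of two groups of units
#' by exchanging group labels.
#'
#' @param lat_a,lat_b latencies (ms) per unit; NAs (no measurable latency)
#'   are dropped.
#' @param n_perm number of permutations (> 0).
#' @param seed integer seed.
#' @return list with `diff` (median A - median B) and `p` (two-sided).
#' @export
latency_compare <- function(lat_a, lat_b, n_perm = 1000, seed = 1L) {
  if (n_perm < 1) stop("`n_perm` must be positive")
  lat_a <- lat_a[!is.na(lat_a)]
  lat_b <- lat_b[!is.na(lat_b)]
  if (length(lat_a) == 0 || length(lat_b) == 0)
    stop("no defined latencies in one of the groups")
  obs <- median(lat_a) - median(lat_b)
  pooled <- c(lat_a, lat_b)
  na <- length(lat_a)
  null <- with_seed(child_seed(seed, 5L), {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample(length(pooled))
      median(pooled[idx[seq_len(na)]]) - median(pooled[idx[-seq_len(na)]])
    }, numeric(1))
  })
  list(diff = obs, p = perm_pvalue(abs(obs), abs(null)))
}

# one-way ANOVA omega-squared from counts and a grouping factor
omega2_oneway <- function(y, g) {
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  n <- length(y)
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tabulate(g)
  ss_between <- sum(ns * (means - gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_within <- ss_total - ss_between
  df_between <- k - 1
  df_within <- n - k
  mse <- ss_within / df_within
  if (ss_total + mse == 0) return(0)
  (ss_between - df_between * mse) / (ss_total + mse)
}

#' Sliding spike-count windows
#'
#' @param range ms range `c(start, end)`.
#' @param width window width, ms.
#' @param step window step, ms.
#' @return data frame with `start`, `end` (half-open windows).
#' @export
sliding_windows <- function(range = c(-100, 400), width = 50, step = 10) {
  starts <- seq(range[1], range[2] - width, by = step)
  data.frame(start = starts, end = starts + width)
}

#' Spike counts in sliding windows
#'
#' @param session a `search_session`.
#' @param unit_id unit identifier.
#' @param trial_ids trial ids.
#' @param windows a [sliding_windows()] data frame.
#' @return trials x windows count matrix with attribute `windows`.
#' @export
sliding_counts <- function(session, unit_id,
                           trial_ids = session$trials$trial_id,
                           windows = sliding_windows()) {
  sp <- session$spikes[[unit_id]]
  if (is.null(sp)) stop("unknown unit: ", unit_id)
  m <- vapply(trial_ids, function(i) {
    s <- sp[[i]]
    vapply(seq_len(nrow(windows)), function(w)
      sum(s >= windows$start[w] & s < windows$end[w]), numeric(1))
  }, numeric(nrow(windows)))
  m <- if (nrow(windows) == 1L) matrix(m, ncol = 1L) else t(m)
  attr(m, "windows") <- windows
  m
}

#' Percent explained variance (omega squared) with permutation z-scoring
#'
#' For each count window, computes the unbiased explained-variance statistic
#' `omega^2 = (SS_between - df * MSE) / (SS_total + MSE)` from a one-way
#' ANOVA of spike counts across levels of a location factor, plus a
#' permutation z-score obtained by shuffling trials across locations
#' (`n_shuffle` label permutations, each applied to all windows).
#' `omega^2` may be negative (unbiased estimator); values are not clipped.
#'
#' @param counts trials x windows count matrix (a vector is treated as one
#'   window). Levels with fewer than 2 trials are dropped with a warning.
#' @param labels location factor, one entry per trial.
#' @param n_shuffle number of label shuffles for the null.
#' @param seed integer seed.
#' @return object of class `pev_result`: data frame with `omega2`, `z` per
#'   window plus attribute `windows` when present on `counts`.
#' @export
pev_omega2 <- function(counts, labels, n_shuffle = 200, seed = 1L) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
  g <- as.factor(labels)
  if (length(g) != nrow(counts)) stop("`labels` must have one entry per trial")
  keep_lv <- names(which(table(g) >= 2))
  if (length(keep_lv) < nlevels(droplevels(g)))
    warning("dropping location levels with fewer than 2 trials")
  keep <- g %in% keep_lv
  counts <- counts[keep, , drop = FALSE]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("omega^2 undefined with fewer than 2 levels")

  obs <- apply(counts, 2, omega2_oneway, g = g)
  null <- with_seed(child_seed(seed, 6L), {
    v <- vapply(seq_len(n_shuffle), function(s) {
      gp <- sample(g)
      apply(counts, 2, omega2_oneway, g = gp)
    }, numeric(ncol(counts)))
    if (ncol(counts) == 1L) matrix(v, ncol = 1L) else t(v)
  })
  mu <- colMeans(null)
  sdn <- apply(null, 2, sd)
  z <- ifelse(sdn > 0, (obs - mu) / sdn, NA_real_)
  out <- data.frame(omega2 = obs, z = z)
  attr(out, "windows") <- attr(counts, "windows")
  class(out) <- c("pev_result", class(out))
  out
}

#' Classify a unit's spatial selectivity
#'
#' A unit is selective for a factor when its z-scored PEV exceeds the
#' one-tailed threshold (default 1.645) in any window within the
#' classification interval (150-200 ms after array onset). Units crossing
#' for both target and singleton location are `mixed`; the comparison is
#' strict, so z exactly at the threshold does not count.
#'
#' @param z_target,z_singleton z-scored PEV values within the classification
#'   window for the target- and singleton-location factors.
#' @param threshold one-tailed z threshold.
#' @return one of `"target"`, `"singleton"`, `"mixed"`, `"nonselective"`.
#' @export
classify_selectivity <- function(z_target, z_singleton, threshold = 1.645) {
  sig_t <- any(z_target > threshold, na.rm = TRUE)
  sig_s <- any(z_singleton > threshold, na.rm = TRUE)
  if (sig_t && sig_s) "mixed"
  else if (sig_t) "target"
  else if (sig_s) "singleton"
  else "nonselective"
}
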