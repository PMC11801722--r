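#' Label trials for decoding
#'
#' Builds per-trial decoding labels. `rf_content` labels singleton-present
#' trials by whether the singleton or a non-salient distractor occupied the
#' RF (first saccade away from the RF, 2 classes). `target_location` and
#' `singleton_location` label singleton-present trials by the target or
#' singleton position within the five contralateral (left-hemifield)
#' locations (5 classes, no RF or saccade filtering).
#'
#' @param session a `search_session`.
#' @param contrast one of `"rf_content"`, `"target_location"`,
#'   `"singleton_location"`.
#' @param positions 0-based positions kept for the location contrasts.
#' @return data frame with `trial_id` and `label` (factor).
#' @export
label_trials <- function(session,
                         contrast = c("rf_content", "target_location",
                                      "singleton_location"),
                         positions = left_hemifield_positions(session$layout)) {
  contrast <- match.arg(contrast)
  tr <- session$trials
  if (contrast == "rf_content") {
    sets <- select_trials(session, "singleton_vs_nonsingleton_rf",
                          min_trials = 0L)
    return(data.frame(
      trial_id = c(sets[[1]], sets[[2]]),
      label = factor(rep(names(sets), times = lengths(sets)))))
  }
  pos <- if (contrast == "target_location") tr$target_pos else tr$singleton_pos
  keep <- tr$display_type == "singleton_present" & pos %in% positions
  data.frame(trial_id = tr$trial_id[keep], label = factor(pos[keep]))
}

#' Build a pseudo-population for decoding
#'
#' Combines units (within or across sessions) into pseudo-trials: for each of
#' `n_resamples` resamples, each unit contributes `n_trials` randomly drawn
#' trials per label (without replacement), giving exact label balance. Units
#' with fewer than `n_trials` trials for any label are excluded and logged.
#' Features are spike counts in sliding windows.
#'
#' @param sessions a `search_session` or list of them.
#' @param contrast passed to [label_trials()], or a list of per-session label
#'   data frames.
#' @param n_trials trials drawn per label and unit.
#' @param n_resamples number of resamples.
#' @param seed integer seed.
#' @param windows a [sliding_windows()] data frame.
#' @return object of class `pseudo_population`: list with `counts` (list over
#'   resamples of units x samples x windows arrays), `labels` (factor, one
#'   per sample), `windows`, `units` (data frame with `session`, `unit_id`,
#'   `included`), `n_trials`.
#' @export
build_pseudopopulation <- function(sessions, contrast = "rf_content",
                                   n_trials = 10L, n_resamples = 50L,
                                   seed = 1L,
                                   windows = sliding_windows()) {
  if (inherits(sessions, "search_session")) sessions <- list(sessions)
  labels <- if (is.list(contrast) && !is.character(contrast)) contrast else
    lapply(sessions, label_trials, contrast = contrast)

  lab_levels <- levels(labels[[1]]$label)
  per_unit <- list()
  unit_log <- list()
  for (si in seq_along(sessions)) {
    ses <- sessions[[si]]
    lab <- labels[[si]]
    for (uid in ses$unit_ids) {
      n_by_label <- table(lab$label)
      ok <- all(n_by_label >= n_trials) && setequal(names(n_by_label), lab_levels)
      unit_log[[length(unit_log) + 1]] <-
        data.frame(session = si, unit_id = uid, included = ok)
      if (!ok) next
      cnt <- sliding_counts(ses, uid, lab$trial_id, windows)
      per_unit[[length(per_unit) + 1]] <- list(counts = cnt, label = lab$label)
    }
  }
  if (length(per_unit) == 0) stop("no unit meets the trials-per-label criterion")

  n_units <- length(per_unit)
  n_samples <- n_trials * length(lab_levels)
  sample_labels <- factor(rep(lab_levels, each = n_trials), levels = lab_levels)

  counts <- with_seed(child_seed(seed, 8L), {
    lapply(seq_len(n_resamples), function(r) {
      arr <- array(0, dim = c(n_units, n_samples, nrow(windows)))
      for (ui in seq_len(n_units)) {
        pu <- per_unit[[ui]]
        rows <- unlist(lapply(lab_levels, function(lv)
          sample(which(pu$label == lv), n_trials)))
        arr[ui, , ] <- pu$counts[rows, , drop = FALSE]
      }
      arr
    })
  })
  structure(list(counts = counts, labels = sample_labels, windows = windows,
                 units = do.call(rbind, unit_log), n_trials = n_trials),
            class = "pseudo_population")
}

#' @export
print.pseudo_population <- function(x, ...) {
  cat("pseudo_population:", dim(x$counts[[1]])[1], "units,",
      length(x$labels), "samples (", nlevels(x$labels), "classes ),",
      length(x$counts), "resamples,", nrow(x$windows), "windows\n")
  invisible(x)
}

# min-max scale features (rows of units x samples matrix) to [0, 1]
minmax_rows <- function(x, ref = x) {
  lo <- apply(ref, 1, min)
  hi <- apply(ref, 1, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  (x - lo) / rng
}

#' Cross-validated linear-SVM accuracy for one feature matrix
#'
#' Linear support vector machine (cost `cost`) with stratified k-fold
#' cross-validation. By default, features are min-max scaled to \[0, 1\]
#' using the range over all samples, the same scaling applied to train and
#' test folds; set `scale_train_only = TRUE` for a leakage-free variant that
#' derives the scaling from the training fold only.
#'
#' @param x units x samples matrix.
#' @param y labels (factor) per sample.
#' @param folds number of CV folds.
#' @param cost SVM cost parameter.
#' @param scale_train_only see description.
#' @param seed integer seed for fold assignment.
#' @return mean accuracy over folds.
#' @export
svm_cv_accuracy <- function(x, y, folds = 5L, cost = 1,
                            scale_train_only = FALSE, seed = 1L) {
  y <- droplevels(factor(y))
  if (min(table(y)) < folds) stop("need at least `folds` samples per label")
  fold_of <- with_seed(child_seed(seed, 9L), {
    f <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      f[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
    f
  })
  if (!scale_train_only) x <- minmax_rows(x)
  correct <- 0L
  for (k in seq_len(folds)) {
    tr <- fold_of != k
    xtr <- x[, tr, drop = FALSE]
    xte <- x[, !tr, drop = FALSE]
    if (scale_train_only) {
      xte <- minmax_rows(xte, ref = xtr)
      xtr <- minmax_rows(xtr)
    }
    fit <- e1071::svm(x = t(xtr), y = y[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
    pred <- stats::predict(fit, t(xte))
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Time-resolved pseudo-population decoding
#'
#' Decodes the pseudo-population labels in each count window with a linear
#' SVM and stratified 5-fold cross-validation, averaging accuracy over folds
#' and resamples.
#'
#' @param pop a [build_pseudopopulation()] result.
#' @param folds CV folds.
#' @param cost SVM cost parameter.
#' @param scale_train_only passed to [svm_cv_accuracy()].
#' @param unit_subset optional integer vector restricting the units used.
#' @param seed integer seed.
#' @return object of class `decoding_result`: list with `accuracy` (windows x
#'   resamples matrix), `mean_accuracy` (per window), `windows`, `chance`.
#' @export
decode_timecourse <- function(pop, folds = 5L, cost = 1,
                              scale_train_only = FALSE, unit_subset = NULL,
                              seed = 1L) {
  nw <- nrow(pop$windows)
  acc <- matrix(NA_real_, nw, length(pop$counts))
  for (r in seq_along(pop$counts)) {
    arr <- pop$counts[[r]]
    if (!is.null(unit_subset)) arr <- arr[unit_subset, , , drop = FALSE]
    for (w in seq_len(nw)) {
      acc[w, r] <- svm_cv_accuracy(arr[, , w, drop = TRUE], pop$labels,
                                   folds = folds, cost = cost,
                                   scale_train_only = scale_train_only,
                                   seed = child_seed(seed, r * nw + w))
    }
  }
  structure(list(accuracy = acc, mean_accuracy = rowMeans(acc),
                 windows = pop$windows,
                 chance = 1 / nlevels(pop$labels)),
            class = "decoding_result")
}

#' Shuffle-null accuracy distribution
#'
#' Builds a null decoding-accuracy distribution per window by permuting the
#' sample labels and re-running the cross-validated decoder, and derives a
#' per-window p-value for the observed mean accuracy by its rank in the
#' null.
#'
#' @param pop a [build_pseudopopulation()] result.
#' @param observed optional `decoding_result` to compare against the null.
#' @param n_shuffles number of label permutations (values below 100 trigger a
#'   warning: p-values become unstable).
#' @param folds,cost,scale_train_only as in [decode_timecourse()].
#' @param seed integer seed.
#' @return list with `null` (n_shuffles x windows matrix) and, when
#'   `observed` is supplied, `p` per window.
#' @export
shuffle_null <- function(pop, observed = NULL, n_shuffles = 500, folds = 5L,
                         cost = 1, scale_train_only = FALSE, seed = 1L) {
  if (n_shuffles < 100) warning("fewer than 100 shuffles: p-values unstable")
  nw <- nrow(pop$windows)
  arr <- pop$counts[[1]]
  null <- with_seed(child_seed(seed, 10L), {
    v <- vapply(seq_len(n_shuffles), function(s) {
      yl <- sample(pop$labels)
      vapply(seq_len(nw), function(w)
        svm_cv_accuracy(arr[, , w, drop = TRUE], yl, folds = folds,
                        cost = cost, scale_train_only = scale_train_only,
                        seed = child_seed(seed, s * nw + w)),
        numeric(1))
    }, numeric(nw))
    if (nw == 1L) matrix(v, ncol = 1L) else t(v)
  })
  out <- list(null = null)
  if (!is.null(observed)) {
    out$p <- vapply(seq_len(nw), function(w)
      perm_pvalue(observed$mean_accuracy[w], null[, w], two_sided = FALSE),
      numeric(1))
  }
  out
}

#' Two-sided cluster-based permutation test over time
#'
#' Corrects for multiple comparisons over time bins when comparing two
#' paired accuracy series (or one series against a chance level). Per bin, a
#' one-sample t statistic of the paired differences across resamples is
#' thresholded at the two-sided `alpha` quantile; contiguous suprathreshold
#' bins form clusters scored by their summed t statistic, and cluster-level
#' p-values come from the permutation distribution of the maximum absolute
#' cluster score under random sign flips of the per-resample difference
#' series.
#'
#' @param series_a resamples x bins accuracy matrix.
#' @param series_b resamples x bins matrix paired with `series_a`, or a
#'   scalar chance level.
#' @param alpha cluster-forming (and cluster-level) significance level.
#' @param n_perm number of sign-flip permutations.
#' @param seed integer seed.
#' @return data frame of clusters (`start_bin`, `end_bin`, `stat`, `p`,
#'   `significant`), possibly empty, with attribute `t` (per-bin statistics).
#' @export
cluster_permutation_test <- function(series_a, series_b = 0.5, alpha = 0.05,
                                     n_perm = 1000, seed = 1L) {
  if (is.matrix(series_b)) {
    if (!all(dim(series_a) == dim(series_b)))
      stop("series length mismatch between conditions")
    d <- series_a - series_b
  } else {
    d <- series_a - series_b[1]
  }
  n <- nrow(d)
  tfun <- function(m) {
    mu <- colMeans(m)
    se <- apply(m, 2, sd) / sqrt(n)
    ifelse(se > 0, mu / se, 0)
  }
  crit <- qt(1 - alpha / 2, n - 1)
  clusters_of <- function(tv) {
    pos <- logical_runs(tv > crit)
    neg <- logical_runs(tv < -crit)
    runs <- rbind(pos, neg)
    if (nrow(runs) == 0) return(runs)
    runs$stat <- vapply(seq_len(nrow(runs)), function(i)
      sum(tv[runs$start[i]:runs$end[i]]), numeric(1))
    runs
  }
  tv <- tfun(d)
  obs <- clusters_of(tv)
  null_max <- with_seed(child_seed(seed, 11L), {
    vapply(seq_len(n_perm), function(i) {
      flip <- sample(c(-1, 1), n, replace = TRUE)
      cl <- clusters_of(tfun(d * flip))
      if (nrow(cl) == 0) 0 else max(abs(cl$stat))
    }, numeric(1))
  })
  if (nrow(obs) == 0) {
    out <- data.frame(start_bin = integer(0), end_bin = integer(0),
                      stat = numeric(0), p = numeric(0),
                      significant = logical(0))
  } else {
    p <- vapply(obs$stat, function(s)
      (sum(null_max >= abs(s)) + 1) / (n_perm + 1), numeric(1))
    out <- data.frame(start_bin = obs$start, end_bin = obs$end,
                      stat = obs$stat, p = p, significant = p < alpha)
    out <- out[order(out$start_bin), ]
    rownames(out) <- NULL
  }
  attr(out, "t") <- tv
  out
}

#' Match unit counts between two populations
#'
#' Subsamples the larger of two unit sets to the size of the smaller, once
#' per resample, for fair between-area decoding comparisons.
#'
#' @param n_a,n_b unit counts of the two populations.
#' @param n_resamples number of resamples.
#' @param seed integer seed.
#' @return list with `a` and `b`: each a list (over resamples) of unit index
#'   vectors of equal length `min(n_a, n_b)`.
#' @export
stratify_units <- function(n_a, n_b, n_resamples = 50L, seed = 1L) {
  if (n_a < 1 || n_b < 1) stop("populations must be non-empty")
  m <- min(n_a, n_b)
  with_seed(child_seed(seed, 12L), {
    list(a = lapply(seq_len(n_resamples), function(i)
           if (n_a > m) sort(sample.int(n_a, m)) else seq_len(n_a)),
         b = lapply(seq_len(n_resamples), function(i)
           if (n_b > m) sort(sample.int(n_b, m)) else seq_len(n_b)))
  })
}
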