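# two-sample pooled-variance t statistics per column; zero where degenerate
columnwise_t <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  ifelse(se > 0, (ma - mb) / se, 0)
}

#' Temporal selectivity profiles (t-values) for clustering
#'
#' For each unit, computes the per-millisecond two-sample t statistic of the
#' smoothed firing rate between two conditions (singleton versus non-salient
#' distractor in the RF by default). Units enter the profile matrix if they
#' (i) pass the visual-responsiveness screen, (ii) have at least `min_trials`
#' trials per condition, (iii) show no baseline difference between the
#' conditions (t test at `baseline_alpha`), and (iv) exhibit significant
#' t-values in at least `n_consec` consecutive 1-ms bins within the profile
#' window.
#'
#' @param session a `search_session`.
#' @param contrast contrast name or [trial_contrast()] list (two conditions).
#' @param window ms window for rate estimation.
#' @param profile_window ms window whose t-values form the profile.
#' @param alpha_bin per-bin two-sided significance level for the inclusion
#'   run (uncorrected).
#' @param n_consec required consecutive significant 1-ms bins.
#' @param baseline_alpha level of the baseline-noise exclusion test.
#' @param baseline_window ms baseline window.
#' @param min_trials minimum trials per condition.
#' @param kernel a [kernel_params()].
#' @return list with `profiles` (included-units x time t-value matrix),
#'   `time`, and `units` (data frame: `unit_id`, `included`, `reason`).
#' @export
compute_t_profiles <- function(session,
                               contrast = "singleton_vs_nonsingleton_rf",
                               window = c(-300, 500),
                               profile_window = c(0, 300),
                               alpha_bin = 0.05,
                               n_consec = 10L,
                               baseline_alpha = 0.1,
                               baseline_window = c(-150, 0),
                               min_trials = 10L,
                               kernel = kernel_params()) {
  sets <- select_trials(session, contrast, min_trials = min_trials)
  if (length(sets) != 2) stop("profile contrast must have exactly 2 conditions")
  ids_a <- sets[[1]]; ids_b <- sets[[2]]

  rows <- list(); info <- list()
  for (uid in session$unit_ids) {
    reason <- NA_character_
    if (length(ids_a) < min_trials || length(ids_b) < min_trials) {
      reason <- "min_trials"
    } else {
      ra <- rate_matrix(session, uid, ids_a, window, kernel)
      rb <- rate_matrix(session, uid, ids_b, window, kernel)
      tt <- attr(ra, "time")
      all_rates <- rbind(ra, rb)
      attr(all_rates, "time") <- tt
      if (!screen_visual_responsive(all_rates)) {
        reason <- "not_responsive"
      } else {
        base_a <- rowMeans(ra[, in_window(tt, baseline_window), drop = FALSE])
        base_b <- rowMeans(rb[, in_window(tt, baseline_window), drop = FALSE])
        noisy <- sd(c(base_a, base_b)) > 0 &&
          t.test(base_a, base_b, var.equal = TRUE)$p.value < baseline_alpha
        if (noisy) {
          reason <- "noisy_baseline"
        } else {
          tv <- columnwise_t(ra, rb)
          df <- nrow(ra) + nrow(rb) - 2
          crit <- qt(1 - alpha_bin / 2, df)
          prof_sel <- in_window(tt, profile_window)
          runs <- logical_runs(abs(tv) > crit & prof_sel)
          if (nrow(runs) == 0 || max(runs$length) < n_consec) {
            reason <- "no_selectivity_run"
          } else {
            rows[[uid]] <- tv[prof_sel]
          }
        }
      }
    }
    info[[uid]] <- data.frame(unit_id = uid, included = is.na(reason),
                              reason = reason)
  }
  grid <- seq(window[1], window[2] - 1L)
  list(profiles = do.call(rbind, rows),
       time = grid[in_window(grid, profile_window)],
       units = do.call(rbind, c(info, list(make.row.names = FALSE))))
}

#' Graph-based clustering of selectivity profiles
#'
#' PhenoGraph-style clustering: for each unit, find its `k` nearest
#' neighbours by Euclidean distance between temporal profiles; connect units
#' to their neighbours with edge weights equal to the Jaccard index of their
#' neighbour sets; partition the resulting weighted graph by Louvain
#' modularity maximisation. The number of clusters is emergent, not preset.
#' Communities smaller than `min_cluster_size` are merged into the cluster
#' with the nearest centroid.
#'
#' @param profiles units x time matrix (rows are units).
#' @param k neighbour count (default 40); must be smaller than the number of
#'   units.
#' @param seed integer seed for the Louvain heuristic.
#' @param resolution Louvain resolution parameter.
#' @param min_cluster_size communities below this size are merged away.
#' @return object of class `cluster_assignment`: list with `labels`
#'   (0-based, contiguous, ordered by decreasing cluster size), `k`,
#'   `modularity`, `n_clusters`.
#' @export
phenograph_cluster <- function(profiles, k = 40L, seed = 1L, resolution = 1,
                               min_cluster_size = 3L) {
  n <- nrow(profiles)
  if (is.null(n) || n <= k)
    stop("need more units than k = ", k, "; reduce k")
  d <- as.matrix(stats::dist(profiles))
  if (max(d) == 0) {
    # all profiles identical: a single community
    return(structure(list(labels = rep(0L, n), k = k, modularity = 0,
                          n_clusters = 1L), class = "cluster_assignment"))
  }
  nn <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, ])
    ord[ord != i][seq_len(k)]
  })

  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    js <- nn[[i]]
    w <- vapply(js, function(j) {
      inter <- length(intersect(nn[[i]], nn[[j]]))
      inter / (2 * k - inter)
    }, numeric(1))
    cbind(pmin(i, js), pmax(i, js), w)
  }))
  edges <- edges[edges[, 3] > 0, , drop = FALSE]
  key <- paste(edges[, 1], edges[, 2])
  edges <- edges[!duplicated(key), , drop = FALSE]

  g <- igraph::graph_from_edgelist(cbind(edges[, 1], edges[, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comm <- with_seed(child_seed(seed, 7L),
    igraph::cluster_louvain(g, weights = edges[, 3],
                            resolution = resolution))
  labels <- igraph::membership(comm)

  # merge undersized communities into the nearest centroid
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_cluster_size]
    if (length(small) == 0 || length(sizes) == 1) break
    s <- small[1]
    idx <- which(labels == as.integer(s))
    cents <- sapply(setdiff(names(sizes), s), function(cl)
      colMeans(profiles[labels == as.integer(cl), , drop = FALSE]))
    for (i in idx) {
      dc <- colSums((cents - profiles[i, ])^2)
      labels[i] <- as.integer(names(which.min(dc)))
    }
  }

  # relabel 0-based by decreasing size (ties: first-appearing cluster)
  sizes <- sort(table(labels), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(remap[as.character(labels)])
  structure(list(labels = labels, k = k,
                 modularity = igraph::modularity(comm),
                 n_clusters = length(unique(labels))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", x$n_clusters, "clusters, k =", x$k,
      ", modularity =", round(x$modularity, 3), "\n")
  print(table(x$labels))
  invisible(x)
}

# average columns of a 1-ms matrix into wider bins; returns matrix + edges
rebin_columns <- function(m, time, bin_ms) {
  edges <- seq(min(time), max(time) + 1, by = bin_ms)
  idx <- findInterval(time, edges)
  out <- sapply(seq_len(length(edges) - 1), function(b)
    rowMeans(m[, idx == b, drop = FALSE]))
  attr(out, "time") <- edges[-length(edges)]
  out
}

#' Per-cluster rate summaries and difference latencies
#'
#' For each cluster, averages baseline-subtracted condition-mean rates across
#' member units, forms the between-condition difference series, and estimates
#' the latency of the difference with [difference_latency()] on 5-ms bins of
#' the per-unit differences.
#'
#' @param labels cluster labels (0-based), one per unit row.
#' @param rates_a,rates_b units x time matrices of per-unit condition-mean
#'   (normalised) rates.
#' @param time ms grid for the rate columns.
#' @param baseline_window ms window whose mean is subtracted per unit and
#'   condition.
#' @param latency_bin_ms bin width for the latency test.
#' @return data frame with one row per cluster and time point
#'   (`cluster`, `time_ms`, `mean_a`, `mean_b`, `difference`, `sem`), with
#'   attribute `latency` (named vector, ms, per cluster).
#' @export
cluster_summaries <- function(labels, rates_a, rates_b, time,
                              baseline_window = c(-150, 0),
                              latency_bin_ms = 5) {
  stopifnot(nrow(rates_a) == length(labels), nrow(rates_b) == length(labels))
  bsel <- in_window(time, baseline_window)
  a0 <- rates_a - rowMeans(rates_a[, bsel, drop = FALSE])
  b0 <- rates_b - rowMeans(rates_b[, bsel, drop = FALSE])
  diffs <- a0 - b0

  out <- list(); lat <- c()
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) == 0) { warning("empty cluster ", cl); next }
    da <- a0[idx, , drop = FALSE]
    db <- b0[idx, , drop = FALSE]
    dd <- diffs[idx, , drop = FALSE]
    out[[length(out) + 1]] <- data.frame(
      cluster = cl, time_ms = time,
      mean_a = colMeans(da), mean_b = colMeans(db),
      difference = colMeans(dd),
      sem = apply(dd, 2, sd) / sqrt(length(idx)))
    lat_cl <- if (length(idx) >= 2) {
      binned <- rebin_columns(dd, time, latency_bin_ms)
      difference_latency(binned)$latency_ms
    } else NA_real_
    lat <- c(lat, stats::setNames(lat_cl, cl))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "latency") <- lat
  res
}
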