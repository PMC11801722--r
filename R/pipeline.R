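#' Pipeline run configuration
#'
#' Collects every tunable parameter of the analysis pipeline with defaults
#' matching the standard analysis settings: Gaussian smoothing sigma 10 ms,
#' minimum 10 trials per condition, 10 trials per label and 50 resamples for
#' decoding, 5-fold cross-validation, 500 shuffle nulls, 1,000 permutations,
#' K = 40 clustering neighbours, d = 5 subspace dimensions and a 1%
#' exclusive-variance cap. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    n_units = 120L,
    cluster_mix = c(suppression = 0.35, early_enh_late_supp = 0.2,
                    enhancement = 0.15, nonselective = 0.3),
    overlap = 0.5,
    d_true = 5L,
    n_trials = c(singleton_present = 150L, singleton_absent = 60L,
                 mixed_color = 60L),
    sigma_ms = 10,
    min_trials = 10L,
    decode_range = c(-100, 400),
    decode_width = 50,
    decode_step = 10,
    n_trials_decode = 10L,
    n_resamples = 50L,
    folds = 5L,
    n_shuffles = 500L,
    n_perm = 1000L,
    knn_k = 40L,
    d = 5L,
    v = 0.01,
    pev_window = c(150, 200),
    pev_shuffles = 200L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "run_config"
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Orchestrates simulate -> preprocess -> unit_stats -> clustering ->
#' decoding -> subspaces -> behavior, writing every output table under
#' `out_dir` together with the serialised configuration; a run is
#' deterministic given `seed`. Stage failures abort with the stage name;
#' outputs of completed stages are preserved.
#'
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @param seed integer seed.
#' @param stages subset of stages to run, in pipeline order.
#' @return invisibly, a list with the in-memory results of the executed
#'   stages.
#' @export
run_pipeline <- function(out_dir, config = run_config(), seed = 0L,
                         stages = c("simulate", "preprocess", "unit_stats",
                                    "clustering", "decoding", "subspaces",
                                    "behavior")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::toJSON(c(unclass(config), list(seed = seed)),
                              auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "config.json"))
  kernel <- kernel_params(config$sigma_ms)
  res <- list()
  report <- c("# Pipeline report", "")

  ses <- pipeline_stage("simulate", {
    pop <- make_unit_population(config$n_units, config$cluster_mix,
                                geometry_spec(config$d_true, config$overlap),
                                seed = child_seed(seed, 100))
    s <- simulate_session(pop, n_trials_per_condition = config$n_trials,
                          seed = child_seed(seed, 101))
    if ("simulate" %in% stages) write_session(s, file.path(out_dir, "session"))
    s
  })
  res$session <- ses
  report <- c(report, sprintf("- session: %d units, %d trials",
                              length(ses$unit_ids), nrow(ses$trials)))

  if (any(c("preprocess", "unit_stats", "clustering") %in% stages)) {
    qc <- pipeline_stage("preprocess", {
      sets <- select_trials(ses, "singleton_vs_nonsingleton_rf",
                            min_trials = config$min_trials)
      do.call(rbind, lapply(ses$unit_ids, function(uid) {
        rates <- rate_matrix(ses, uid, unlist(sets), kernel = kernel)
        responsive <- screen_visual_responsive(rates)
        nf <- normalize_unit(list(all = rates))
        data.frame(unit_id = uid, responsive = responsive,
                   norm_factor = nf$norm_factor,
                   excluded = nf$excluded || !attr(sets, "included"),
                   reason = if (!attr(sets, "included")) "min_trials"
                            else if (nf$excluded) "zero_response"
                            else NA_character_)
      }))
    })
    write.csv(qc, file.path(out_dir, "unit_qc.csv"), row.names = FALSE)
    res$unit_qc <- qc
  }

  if ("unit_stats" %in% stages) {
    stats_df <- pipeline_stage("unit_stats", {
      sets <- select_trials(ses, "singleton_vs_nonsingleton_rf",
                            min_trials = config$min_trials)
      win <- config$pev_window
      wdf <- data.frame(start = win[1], end = win[2])
      lab_t <- label_trials(ses, "target_location")
      lab_s <- label_trials(ses, "singleton_location")
      do.call(rbind, lapply(seq_along(ses$unit_ids), function(ui) {
        uid <- ses$unit_ids[ui]
        fr <- function(ids) mean(rate_matrix(ses, uid, ids,
                                             c(win[1], win[2]), kernel))
        mi <- if (attr(sets, "included"))
          modulation_index(fr(sets[[1]]), fr(sets[[2]])) else NA_real_
        zt <- pev_omega2(sliding_counts(ses, uid, lab_t$trial_id, wdf),
                         lab_t$label, n_shuffle = config$pev_shuffles,
                         seed = child_seed(seed, 200 + ui))$z
        zs <- pev_omega2(sliding_counts(ses, uid, lab_s$trial_id, wdf),
                         lab_s$label, n_shuffle = config$pev_shuffles,
                         seed = child_seed(seed, 500 + ui))$z
        data.frame(unit_id = uid, contrast = "singleton_vs_nonsingleton_rf",
                   modulation_index = mi, z_pev_target = zt,
                   z_pev_singleton = zs,
                   selectivity_class = classify_selectivity(zt, zs))
      }))
    })
    write.csv(stats_df, file.path(out_dir, "unit_stats.csv"), row.names = FALSE)
    res$unit_stats <- stats_df
    report <- c(report, "- selectivity classes:",
                paste0("  - ", names(table(stats_df$selectivity_class)), ": ",
                       table(stats_df$selectivity_class)))
  }

  if ("clustering" %in% stages) {
    cl <- pipeline_stage("clustering", {
      prof <- compute_t_profiles(ses, min_trials = config$min_trials,
                                 kernel = kernel)
      if (is.null(prof$profiles) || nrow(prof$profiles) < 10)
        stop("too few units pass the profile inclusion criteria")
      k <- min(config$knn_k, nrow(prof$profiles) - 1L)
      asg <- phenograph_cluster(prof$profiles, k = k,
                                seed = child_seed(seed, 102))
      list(profiles = prof, assignment = asg)
    })
    clusters <- data.frame(unit_id = rownames(cl$profiles$profiles),
                           cluster_label = cl$assignment$labels)
    write.csv(clusters, file.path(out_dir, "clusters.csv"), row.names = FALSE)
    res$clustering <- cl
    report <- c(report, sprintf("- clustering: %d clusters (modularity %.3f)",
                                cl$assignment$n_clusters,
                                cl$assignment$modularity))
  }

  if ("decoding" %in% stages) {
    dec <- pipeline_stage("decoding", {
      wins <- sliding_windows(config$decode_range, config$decode_width,
                              config$decode_step)
      pop <- build_pseudopopulation(ses, "rf_content",
                                    n_trials = config$n_trials_decode,
                                    n_resamples = config$n_resamples,
                                    seed = child_seed(seed, 103),
                                    windows = wins)
      obs <- decode_timecourse(pop, folds = config$folds,
                               seed = child_seed(seed, 104))
      sig <- cluster_permutation_test(t(obs$accuracy), obs$chance,
                                      n_perm = config$n_perm,
                                      seed = child_seed(seed, 105))
      list(pop = pop, result = obs, clusters = sig)
    })
    acc <- dec$result$accuracy
    long <- data.frame(
      contrast = "rf_content",
      window_start_ms = rep(dec$result$windows$start, ncol(acc)),
      resample = rep(seq_len(ncol(acc)), each = nrow(acc)),
      accuracy = as.vector(acc))
    write.csv(long, file.path(out_dir, "decoding.csv"), row.names = FALSE)
    sig <- dec$clusters
    sig_json <- lapply(seq_len(nrow(sig)), function(i) list(
      start_ms = dec$result$windows$start[sig$start_bin[i]],
      end_ms = dec$result$windows$end[sig$end_bin[i]],
      p = sig$p[i]))
    writeLines(jsonlite::toJSON(sig_json, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "decoding_sig.json"))
    res$decoding <- dec
    report <- c(report, sprintf("- decoding: peak accuracy %.2f (chance %.2f)",
                                max(dec$result$mean_accuracy),
                                dec$result$chance))
  }

  if ("subspaces" %in% stages) {
    sub <- pipeline_stage("subspaces", {
      if (config$d > length(ses$unit_ids))
        stop("subspace dimension d exceeds the number of units")
      mt <- build_condition_matrix(ses, "target", kernel = kernel)
      ms <- build_condition_matrix(ses, "singleton", kernel = kernel)
      cov <- covariance_pair(mt, ms)
      orth <- fit_orthogonal_pair(cov, d = config$d,
                                  seed = child_seed(seed, 106))
      ex_t <- fit_exclusive(cov$target, cov$singleton, v = config$v,
                            d = config$d, seed = child_seed(seed, 107))
      ex_s <- fit_exclusive(cov$singleton, cov$target, v = config$v,
                            d = config$d, seed = child_seed(seed, 108))
      sh <- fit_shared(cov, ex_t$q, ex_s$q, d = config$d)
      list(cov = cov, orth = orth, excl_target = ex_t, excl_singleton = ex_s,
           shared = sh, weights = unit_weights(sh$q))
    })
    rep_json <- list(
      alignment = as.list(sub$orth$alignment),
      exclusive = list(
        target = list(alignment_max = sub$excl_target$alignment_max,
                      alignment_limit = sub$excl_target$alignment_limit),
        singleton = list(alignment_max = sub$excl_singleton$alignment_max,
                         alignment_limit = sub$excl_singleton$alignment_limit)),
      shared = as.list(sub$shared$alignment),
      orthogonality_residual = sub$shared$orthogonality_residual,
      objective = sub$orth$objective,
      weights = sub$weights$weights)
    writeLines(jsonlite::toJSON(rep_json, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "subspace_report.json"))
    res$subspaces <- sub
    report <- c(report,
                sprintf("- subspaces: own-context alignment %.2f / %.2f, cross %.2f / %.2f",
                        sub$orth$alignment["target_on_orth_target"],
                        sub$orth$alignment["singleton_on_orth_singleton"],
                        sub$orth$alignment["singleton_on_orth_target"],
                        sub$orth$alignment["target_on_orth_singleton"]))
  }

  if ("behavior" %in% stages) {
    beh <- pipeline_stage("behavior", {
      summ <- summarize_behavior(ses)
      split <- median_split(ses)
      contrast <- median_split_contrast(ses, split,
                                        min_trials = config$min_trials,
                                        kernel = kernel)
      list(summary = summ, split = split, contrast = contrast)
    })
    write.csv(data.frame(
      first_saccade_to_singleton = beh$summary$first_saccade_to_singleton_rate,
      chisq_p = beh$summary$chisq_vs_random$p,
      median_search_present = beh$summary$median_search_time[["singleton_present"]],
      median_search_absent = beh$summary$median_search_time[["singleton_absent"]]),
      file.path(out_dir, "behavior.csv"), row.names = FALSE)
    write.csv(beh$split, file.path(out_dir, "speed_split.csv"),
              row.names = FALSE)
    res$behavior <- beh
    report <- c(report, sprintf(
      "- behavior: first saccade to singleton %.1f%%, median fast/slow MI %.3f",
      100 * beh$summary$first_saccade_to_singleton_rate,
      median(beh$contrast$mi, na.rm = TRUE)))
  }

  writeLines(report, file.path(out_dir, "report.md"))
  invisible(res)
}
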