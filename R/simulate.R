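# visual-response onset profile: 0 before 40 ms, full by 60 ms
visual_onset_profile <- function(t) pmin(pmax((t - 40) / 20, 0), 1)

#' Generate a synthetic eye-position trace
#'
#' Produces a 120-Hz eye trace consisting of fixational jitter plus
#' sigmoidal saccadic displacements. Saccade durations scale with amplitude
#' (`10 + 2 * amplitude` ms) so that peak velocity exceeds the 50 deg/s
#' detection threshold for amplitudes of 1 degree and above.
#'
#' Randomness (the jitter) is drawn from the current RNG state; seed the
#' stream with [set.seed()] or call from within a seeded generator.
#'
#' @param t_range ms window `c(start, end)` covered by the trace.
#' @param saccade_plan data frame with columns `onset` (ms, strictly
#'   increasing), `amplitude` (deg) and `direction_deg`; may have zero rows.
#' @param fs_hz sampling rate, Hz.
#' @param jitter_sd fixational jitter SD, degrees, per sample and axis.
#' @param start_xy fixation position at trace start.
#' @return data frame with columns `t_ms`, `x_deg`, `y_deg`.
#' @export
generate_eye_trace <- function(t_range, saccade_plan = NULL, fs_hz = 120,
                               jitter_sd = 0.02, start_xy = c(0, 0)) {
  dt <- 1000 / fs_hz
  t <- seq(t_range[1], t_range[2], by = dt)
  x <- rep(start_xy[1], length(t))
  y <- rep(start_xy[2], length(t))
  if (!is.null(saccade_plan) && nrow(saccade_plan) > 0) {
    ons <- saccade_plan$onset
    if (is.unsorted(ons, strictly = TRUE)) stop("saccade onsets must be strictly increasing")
    dur <- 10 + 2 * saccade_plan$amplitude
    if (any(ons[-1] < (ons + dur)[-length(ons)]))
      stop("overlapping saccades in plan")
    for (i in seq_along(ons)) {
      s <- dur[i] / 8
      disp <- saccade_plan$amplitude[i] *
        plogis((t - ons[i] - dur[i] / 2) / s)
      th <- saccade_plan$direction_deg[i] * pi / 180
      x <- x + disp * cos(th)
      y <- y + disp * sin(th)
    }
  }
  x <- x + rnorm(length(t), 0, jitter_sd)
  y <- y + rnorm(length(t), 0, jitter_sd)
  data.frame(t_ms = t, x_deg = x, y_deg = y)
}

# per-trial firing-rate profile (spikes/s) on a 1-ms grid
trial_rate_profile <- function(arch, grid, target_pos, singleton_pos,
                               singleton_in_rf, rate_scale, supp_jitter = 0,
                               rate_floor = 0.5) {
  alpha <- visual_onset_profile(grid)
  sg <- rep(1, length(grid))
  if (singleton_in_rf) {
    g <- archetype_gain(arch$cluster_id, grid)
    sg <- pmax(1 + (g - 1) * (1 + supp_jitter), 0.05)
  }
  tune <- arch$location_tuning$target[target_pos + 1L]
  if (!is.na(singleton_pos))
    tune <- tune + arch$location_tuning$singleton[singleton_pos + 1L]
  r <- arch$baseline_rate * (1 + (arch$visual_gain - 1) * alpha) * sg +
    rate_scale * alpha * tune
  pmax(r, rate_floor)
}

# balanced, shuffled assignment of n values over the position set
balanced_positions <- function(n, positions) {
  sample(rep(positions, length.out = max(n, length(positions))))[seq_len(n)]
}

#' Simulate a recording session of the singleton search task
#'
#' Generates inhomogeneous-Poisson spike trains for a population of
#' archetype units performing the 8-stimulus search task with three display
#' types (singleton present, singleton absent, mixed colour), together with
#' trial metadata and 120-Hz eye traces.
#'
#' Per trial, the rate of unit *i* is
#' `baseline * (1 + (visual_gain - 1) * a(t)) * s(t) + rate_scale * a(t) * w`,
#' where `a(t)` is the visual onset profile, `s(t)` the archetype singleton
#' gain (applied when the singleton occupies the RF), and `w` the planted
#' location-tuning weight for the trial's target and singleton positions.
#' A per-trial latent efficacy `e ~ N(0, 1)` deepens or shallows the
#' singleton gain (`behavior$coupling`) and shortens or lengthens search time
#' (`behavior$search_beta`), planting the coupling between distractor
#' suppression and search speed.
#'
#' @param population a [make_unit_population()] result.
#' @param layout a [task_layout()].
#' @param n_trials_per_condition trials per display type: a single count or a
#'   named vector over `c("singleton_present", "singleton_absent",
#'   "mixed_color")`. Every requested condition must have at least one trial.
#' @param seed integer seed; the session is fully reproducible from it.
#' @param window ms range `c(start, end)` over which spikes are simulated,
#'   relative to array onset; must lie within \[-500, 3500\].
#' @param behavior list of behavioural-model parameters: `p_first_target`,
#'   `p_first_singleton` (first-saccade destination probabilities),
#'   `saccade_latency_meanlog`/`_sdlog` (ms), `search_time_median` (named,
#'   ms, per display type), `search_time_sdlog`, `search_beta` (coupling of
#'   log search time to the latent suppression efficacy), `coupling`
#'   (strength of the per-trial singleton-gain modulation).
#' @param eye_jitter_sd fixational jitter SD in degrees.
#' @return an object of class `search_session`.
#' @export
simulate_session <- function(population, layout = task_layout(),
                             n_trials_per_condition = 40L,
                             seed = 1L,
                             window = c(-500, 600),
                             behavior = list(),
                             eye_jitter_sd = 0.02) {
  displays <- c("singleton_present", "singleton_absent", "mixed_color")
  n_cond <- n_trials_per_condition
  if (length(n_cond) == 1L && is.null(names(n_cond)))
    n_cond <- stats::setNames(rep(as.integer(n_cond), 3L), displays)
  if (!all(names(n_cond) %in% displays)) stop("unknown display type in `n_trials_per_condition`")
  if (any(n_cond < 1L))
    stop("zero trials requested for condition: ",
         paste(names(n_cond)[n_cond < 1L], collapse = ", "))
  if (window[1] < -500 || window[2] > 3500) stop("`window` must lie within [-500, 3500] ms")

  beh <- utils::modifyList(list(
    p_first_target = 0.6,
    p_first_singleton = 0.015,
    saccade_latency_meanlog = log(200), saccade_latency_sdlog = 0.15,
    search_time_median = c(singleton_present = 340, singleton_absent = 380,
                           mixed_color = 360),
    search_time_sdlog = 0.3,
    search_beta = 0.25,
    coupling = 0.6
  ), behavior)

  with_seed(child_seed(seed, 2L), {
    trials <- do.call(rbind, lapply(names(n_cond), function(dt) {
      n <- n_cond[[dt]]
      tp <- balanced_positions(n, 0:(layout$n_positions - 1L))
      sp <- if (dt == "singleton_absent") rep(NA_integer_, n) else
        vapply(tp, function(p) {
          sample(setdiff(0:(layout$n_positions - 1L), p), 1L)
        }, integer(1))
      data.frame(display_type = dt, target_pos = tp, singleton_pos = sp)
    }))
    trials <- trials[sample(nrow(trials)), ]
    trials$trial_id <- seq_len(nrow(trials))
    rownames(trials) <- NULL

    rf <- layout$rf_position
    trials$rf_content <- ifelse(trials$target_pos == rf, "target",
                         ifelse(!is.na(trials$singleton_pos) & trials$singleton_pos == rf,
                                "salient_distractor", "nonsalient_distractor"))

    # latent suppression efficacy per trial
    eff <- rnorm(nrow(trials))

    # first-saccade destination
    n_t <- nrow(trials)
    u <- runif(n_t)
    fs_pos <- integer(n_t)
    for (i in seq_len(n_t)) {
      tp <- trials$target_pos[i]; sp <- trials$singleton_pos[i]
      p_sing <- if (is.na(sp)) 0 else beh$p_first_singleton
      if (u[i] < beh$p_first_target) {
        fs_pos[i] <- tp
      } else if (u[i] < beh$p_first_target + p_sing) {
        fs_pos[i] <- sp
      } else {
        others <- setdiff(0:(layout$n_positions - 1L), c(tp, sp))
        fs_pos[i] <- sample(others, 1L)
      }
    }
    trials$first_saccade_pos <- fs_pos
    trials$first_saccade_dir <- ifelse(fs_pos == rf, "toward_rf", "away_from_rf")

    # search time: log-normal, location shortened by suppression efficacy on
    # singleton-bearing displays
    med <- beh$search_time_median[trials$display_type]
    has_sing <- !is.na(trials$singleton_pos)
    meanlog <- log(med) - beh$search_beta * eff * has_sing
    trials$search_time <- rlnorm(n_t, meanlog, beh$search_time_sdlog)
    trials$first_saccade_latency <- rlnorm(n_t, beh$saccade_latency_meanlog,
                                           beh$saccade_latency_sdlog)
    trials$search_time <- pmax(trials$search_time,
                               trials$first_saccade_latency + 80)

    # spikes: per-unit (trials x ms) Poisson counts
    grid <- seq(window[1], window[2] - 1L)
    spikes <- vector("list", population$n_units)
    for (ui in seq_len(population$n_units)) {
      arch <- population$archetypes[[ui]]
      rate <- matrix(0, n_t, length(grid))
      for (i in seq_len(n_t)) {
        rate[i, ] <- trial_rate_profile(
          arch, grid, trials$target_pos[i], trials$singleton_pos[i],
          singleton_in_rf = has_sing[i] && trials$singleton_pos[i] == rf,
          rate_scale = population$rate_scale,
          supp_jitter = beh$coupling * eff[i])
      }
      counts <- matrix(rpois(length(rate), rate / 1000), n_t, length(grid))
      spikes[[ui]] <- lapply(seq_len(n_t), function(i) {
        idx <- which(counts[i, ] > 0)
        rep(grid[idx] + 0.5, counts[i, idx])
      })
    }
    names(spikes) <- paste0("u", seq_len(population$n_units))

    # eye traces: fixation, first saccade, then a corrective saccade to the
    # target when the first saccade went elsewhere
    ecc <- layout$eccentricity_deg
    eye <- lapply(seq_len(n_t), function(i) {
      plan <- data.frame(onset = trials$first_saccade_latency[i],
                         amplitude = ecc,
                         direction_deg = layout$angles_deg[fs_pos[i] + 1L])
      if (fs_pos[i] != trials$target_pos[i]) {
        on2 <- max(trials$search_time[i],
                   plan$onset[1] + 10 + 2 * ecc + 25)
        ang1 <- layout$angles_deg[fs_pos[i] + 1L] * pi / 180
        ang2 <- layout$angles_deg[trials$target_pos[i] + 1L] * pi / 180
        v <- ecc * c(cos(ang2) - cos(ang1), sin(ang2) - sin(ang1))
        plan <- rbind(plan, data.frame(
          onset = on2, amplitude = sqrt(sum(v^2)),
          direction_deg = atan2(v[2], v[1]) * 180 / pi))
      }
      generate_eye_trace(c(max(window[1], -300), min(window[2], 1200) + 200),
                         plan, jitter_sd = eye_jitter_sd)
    })

    structure(list(
      unit_ids = names(spikes),
      trials = trials,
      spikes = spikes,
      eye = eye,
      layout = layout,
      population = population,
      window = window,
      behavior = beh,
      rng_seed = seed
    ), class = "search_session")
  })
}

#' @export
print.search_session <- function(x, ...) {
  cat("search_session:", length(x$unit_ids), "units,", nrow(x$trials), "trials\n")
  print(table(x$trials$display_type))
  cat("spike window [", x$window[1], ",", x$window[2], ") ms, seed", x$rng_seed, "\n")
  invisible(x)
}
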