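test_that("population respects a degenerate cluster mix and rejects bad mixes", {
  pop <- make_unit_population(100, cluster_mix = c(suppression = 1), seed = 1)
  expect_length(pop$archetypes, 100)
  expect_true(all(pop$cluster_ids == "suppression"))

  expect_error(make_unit_population(10, cluster_mix = c(suppression = 0.6)),
               "sum to 1")
  expect_error(make_unit_population(10, cluster_mix = c(suppression = -0.2,
                                                        enhancement = 1.2)),
               "non-negative")
})

test_that("planted bases realise the requested principal angles", {
  pop0 <- make_unit_population(40, geometry = geometry_spec(5, 0), seed = 2)
  ang0 <- principal_angles(pop0$bases$target, pop0$bases$singleton)
  expect_equal(ang0, rep(90, 5), tolerance = 1e-8)

  pop1 <- make_unit_population(40, geometry = geometry_spec(5, 1), seed = 2)
  ang1 <- principal_angles(pop1$bases$target, pop1$bases$singleton)
  expect_lt(max(ang1), 1e-3)
})

test_that("noiseless condition patterns recover the overlap-angle mapping", {
  for (ov in c(0, 0.25, 0.5, 0.75, 1)) {
    pop <- make_unit_population(60, geometry = geometry_spec(5, ov), seed = 3)
    ang <- principal_angles(t(planted_condition_patterns(pop, "target")),
                            t(planted_condition_patterns(pop, "singleton")))
    expect_lt(max(abs(ang - overlap_to_angle(ov))), 1)
  }
})

test_that("spike generation is Poisson: mean and Fano factor", {
  pop <- make_unit_population(2, cluster_mix = c(nonselective = 1),
                              geometry = geometry_spec(1, 0), seed = 4,
                              baseline_range = c(20, 20),
                              visual_gain_range = c(1, 1), tuning_sd = 0)
  ses <- simulate_session(
    pop, n_trials_per_condition = c(singleton_present = 200,
                                    singleton_absent = 200, mixed_color = 200),
    seed = 5, window = c(-500, 500))
  counts <- vapply(ses$spikes[[1]],
                   function(s) sum(s >= -500 & s < 500), numeric(1))
  # 1 s at 20 sp/s: mean 20, SE sqrt(20/600)
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / length(counts)))
  fano <- var(counts) / mean(counts)
  expect_gt(fano, 0.8)
  expect_lt(fano, 1.2)
})

test_that("suppression archetypes fire less with the singleton in the RF", {
  fx <- fixture_suppression_session()
  sets <- select_trials(fx$ses, "singleton_vs_nonsingleton_rf")
  mean_rate <- function(uid, ids)
    mean(rate_matrix(fx$ses, uid, ids, c(150, 200)))
  mis <- vapply(fx$ses$unit_ids, function(u)
    modulation_index(mean_rate(u, sets$singleton_in_rf),
                     mean_rate(u, sets$nonsingleton_in_rf)), numeric(1))
  expect_lt(median(mis), 0)
})

test_that("simulation is deterministic and serialisation byte-identical", {
  pop <- make_unit_population(5, seed = 6, geometry = geometry_spec(2, 0.5))
  s1 <- simulate_session(pop, n_trials_per_condition = 10, seed = 7,
                         window = c(-300, 300))
  s2 <- simulate_session(pop, n_trials_per_condition = 10, seed = 7,
                         window = c(-300, 300))
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$trials, s2$trials)

  d1 <- file.path(tempdir(), "ses_a")
  d2 <- file.path(tempdir(), "ses_b")
  write_session(s1, d1)
  write_session(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("session round-trips through the plain-text format", {
  pop <- make_unit_population(4, seed = 8, geometry = geometry_spec(2, 0.5))
  ses <- simulate_session(pop, n_trials_per_condition = 5, seed = 9,
                          window = c(-300, 300))
  dir <- file.path(tempdir(), "ses_rt")
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(back$trials$target_pos, ses$trials$target_pos)
  expect_equal(back$trials$search_time, ses$trials$search_time,
               tolerance = 1e-12)
  expect_equal(lapply(back$spikes, lapply, as.numeric),
               lapply(ses$spikes, lapply, as.numeric), tolerance = 1e-12)
  expect_equal(back$rng_seed, ses$rng_seed)
})

test_that("requesting zero trials for a condition names the condition", {
  pop <- make_unit_population(2, seed = 10, geometry = geometry_spec(1, 0))
  expect_error(
    simulate_session(pop, n_trials_per_condition = c(
      singleton_present = 10, singleton_absent = 0, mixed_color = 5)),
    "singleton_absent")
})

test_that("spike times stay inside the simulation window", {
  fx <- fixture_session()
  all_sp <- unlist(fx$ses$spikes)
  expect_true(all(all_sp >= -500 & all_sp <= 3500))
  expect_true(all(all_sp >= fx$ses$window[1] & all_sp < fx$ses$window[2]))
})

test_that("eye traces realise planned saccades", {
  tr <- with_seed_test(1, generate_eye_trace(
    c(-300, 600), data.frame(onset = 200, amplitude = 6, direction_deg = 0),
    jitter_sd = 0.02))
  late <- tr$x_deg[tr$t_ms > 280]
  expect_equal(mean(late), 6, tolerance = 0.1)

  # empty plan: pure fixation jitter stays below the saccade threshold
  tr0 <- with_seed_test(2, generate_eye_trace(c(-300, 600), NULL,
                                              jitter_sd = 0.05))
  v <- detect_saccades(tr0)
  expect_equal(nrow(v), 0)

  # two saccades in the same direction: monotone cumulative displacement
  plan <- data.frame(onset = c(100, 300), amplitude = c(3, 3),
                     direction_deg = c(0, 0))
  tr2 <- with_seed_test(3, generate_eye_trace(c(0, 600), plan,
                                              jitter_sd = 0.001))
  expect_equal(tr2$x_deg[length(tr2$x_deg)], 6, tolerance = 0.05)
  expect_true(all(diff(tr2$x_deg) > -0.05))

  expect_error(generate_eye_trace(c(0, 500), data.frame(
    onset = c(100, 105), amplitude = c(6, 6), direction_deg = c(0, 0))),
    "overlap")
  expect_error(generate_eye_trace(c(0, 500), data.frame(
    onset = c(300, 100), amplitude = c(2, 2), direction_deg = c(0, 0))),
    "increasing")
})
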