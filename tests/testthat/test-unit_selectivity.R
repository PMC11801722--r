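test_that("modulation index matches its closed form and is antisymmetric", {
  expect_equal(modulation_index(10, 10), 0)
  expect_equal(modulation_index(15, 5), 0.5)
  expect_equal(modulation_index(0, 8), -1)
  expect_true(is.na(modulation_index(0, 0)))
  expect_error(modulation_index(-1, 2), "non-negative")

  x <- with_seed_test(1, runif(50, 0, 60))
  y <- with_seed_test(2, runif(50, 0, 60))
  expect_equal(modulation_index(x, y), -modulation_index(y, x))
  expect_true(all(abs(modulation_index(x, y)) <= 1))
})

test_that("rank effect size reproduces reported values under z/sqrt(n)", {
  expect_equal(round(rank_effect_size(-4.8, 219), 2), -0.32)
  expect_equal(round(rank_effect_size(-2.2, 191), 2), -0.16)
  expect_equal(rank_effect_size(0, 57), 0)
  expect_error(rank_effect_size(1, 0), ">= 1")
})

test_that("criterion-sweep AUROC equals Mann-Whitney enumeration exhaustively", {
  # every pair of count vectors with entries 0..3 and sizes up to 3,
  # plus random sets with sizes up to 6
  vals <- 0:3
  small_sets <- unlist(lapply(1:3, function(n)
    asplit(as.matrix(expand.grid(rep(list(vals), n))), 1)), recursive = FALSE)
  idx <- with_seed_test(3, sample(length(small_sets), 40))
  for (i in idx) for (j in idx) {
    a <- as.numeric(small_sets[[i]])
    b <- as.numeric(small_sets[[j]])
    expect_equal(auroc(a, b), auroc_enumeration(a, b), tolerance = 1e-12)
  }
  for (r in 1:50) {
    a <- with_seed_test(100 + r, rpois(sample(1:6, 1), 3))
    b <- with_seed_test(200 + r, rpois(sample(1:6, 1), 3))
    expect_equal(auroc(a, b), auroc_enumeration(a, b), tolerance = 1e-12)
    expect_equal(auroc_rank(a, b), auroc_enumeration(a, b), tolerance = 1e-12)
  }
  # frozen example from the enumeration oracle
  expect_equal(auroc(c(1, 2, 3), c(2, 3, 4)), 2 / 9, tolerance = 1e-12)
})

test_that("time-resolved AUROC behaves at the extremes and under the null", {
  a <- with_seed_test(4, matrix(rpois(20 * 30, 5), 20))
  b <- with_seed_test(5, matrix(rpois(20 * 30, 5), 20))
  res <- time_resolved_auroc(a, b, n_shuffles = 50, seed = 1)
  se <- sd(res$auroc) / sqrt(length(res$auroc))
  expect_lt(abs(mean(res$auroc) - 0.5), 2 * se + 0.02)

  hi <- matrix(10:19, 10, 5)
  lo <- matrix(0:9, 10, 5)
  expect_equal(time_resolved_auroc(hi, lo, n_shuffles = 10)$auroc, rep(1, 5))
})

test_that("population AUROC test flags a planted interval and respects the null", {
  n_units <- 30; nb <- 20; ns <- 100
  nulls <- with_seed_test(6, array(0.5 + rnorm(n_units * nb * ns, 0, 0.05),
                                   c(n_units, nb, ns)))
  effect_bins <- 8:12
  aurocs <- with_seed_test(7, {
    a <- matrix(0.5 + rnorm(n_units * nb, 0, 0.05), n_units, nb)
    a[, effect_bins] <- a[, effect_bins] - 0.2
    a
  })
  res <- population_auroc_test(aurocs, nulls, n_population_nulls = 500, seed = 2)
  expect_true(all(res$significant[effect_bins]))
  expect_false(any(res$significant[-effect_bins]))

  null_obs <- with_seed_test(8, matrix(0.5 + rnorm(n_units * nb, 0, 0.05),
                                       n_units, nb))
  res0 <- population_auroc_test(null_obs, nulls, n_population_nulls = 500,
                                seed = 3)
  expect_lte(mean(res0$significant), 0.05)
})

test_that("difference latency finds the first 5-bin significant run", {
  nbins <- 60                      # 5-ms bins over [0, 300)
  tt <- seq(0, by = 5, length.out = nbins)
  mk <- function(onset_bin, effect = 1, n = 40, sd = 1, seed = 9) {
    d <- with_seed_test(seed, matrix(rnorm(n * nbins, 0, sd), n, nbins))
    if (!is.na(onset_bin)) d[, onset_bin:nbins] <- d[, onset_bin:nbins] + effect
    attr(d, "time") <- tt
    d
  }
  expect_equal(difference_latency(mk(17))$latency_ms, 80)

  short <- mk(NA)
  short[, 20:23] <- short[, 20:23] + 50     # 4-bin run only
  attr(short, "time") <- tt
  expect_true(is.na(difference_latency(short)$latency_ms))

  false_runs <- sum(vapply(1:40, function(i)
    !is.na(difference_latency(mk(NA, seed = 100 + i))$latency_ms), logical(1)))
  expect_lte(false_runs / 40, 0.05)

  tiny <- mk(1)[, 1:4]
  attr(tiny, "time") <- tt[1:4]
  expect_error(difference_latency(tiny), "fewer bins")
})

test_that("latency comparison is calibrated and detects planted offsets", {
  g <- with_seed_test(10, 100 + 5 * round(rnorm(30)))
  same <- latency_compare(g, g, n_perm = 400, seed = 1)
  expect_gt(same$p, 0.5)

  a <- with_seed_test(11, 60 + 5 * round(rnorm(30)))
  b <- a + 40
  shift <- latency_compare(a, b, n_perm = 400, seed = 2)
  expect_lt(shift$p, 0.01)
  expect_equal(shift$diff, -40)

  expect_error(latency_compare(a, b, n_perm = 0), "positive")
  expect_error(latency_compare(NA_real_, b), "no defined latencies")
})

test_that("omega^2 equals the direct ANOVA oracle and has closed-form limits", {
  g <- rep(1:5, each = 20)
  y <- with_seed_test(12, rpois(100, 5 + 2 * g))
  expect_equal(unname(omega2_anova_oracle(y, g)),
               pev_omega2(y, g, n_shuffle = 10)$omega2,
               tolerance = 1e-10)

  # distinct constant levels: MSE = 0, omega^2 = 1
  yc <- rep(c(2, 5, 9), each = 3)
  expect_equal(pev_omega2(yc, rep(1:3, each = 3), n_shuffle = 10)$omega2, 1)

  # translation invariance and the upper bound
  expect_equal(pev_omega2(y + 7, g, n_shuffle = 10)$omega2,
               pev_omega2(y, g, n_shuffle = 10)$omega2, tolerance = 1e-10)
  for (r in 1:20) {
    yr <- with_seed_test(300 + r, rnorm(40, rep(rnorm(4, 0, 2), each = 10)))
    expect_lte(pev_omega2(yr, rep(1:4, each = 10), n_shuffle = 5)$omega2, 1)
  }

  expect_error(pev_omega2(y, rep(1, 100)), "fewer than 2 levels")
  expect_warning(pev_omega2(y, c(rep(1:2, each = 49), 3, 3), n_shuffle = 5),
                 NA)
  expect_warning(pev_omega2(y[1:41], c(rep(1:2, each = 20), 3), n_shuffle = 5),
                 "fewer than 2 trials")
})

test_that("z-scored PEV is centred under the null", {
  zs <- with_seed_test(13, vapply(1:40, function(i) {
    y <- rpois(50, 5)
    pev_omega2(y, rep(1:5, each = 10), n_shuffle = 100, seed = i)$z
  }, numeric(1)))
  expect_lt(abs(mean(zs)), 2 / sqrt(length(zs)) + 0.2)
})

test_that("selectivity classification follows the strict one-tailed threshold", {
  expect_equal(classify_selectivity(3, 3), "mixed")
  expect_equal(classify_selectivity(3, 0), "target")
  expect_equal(classify_selectivity(0, 3), "singleton")
  expect_equal(classify_selectivity(1.6, 1.6), "nonselective")
  expect_equal(classify_selectivity(1.645, 1.645), "nonselective")
})

test_that("planted selectivity classes are recovered majority-correct", {
  pop <- make_unit_population(
    40, seed = 14,
    selectivity_mix = c(target = 0.25, singleton = 0.25, mixed = 0.25,
                        nonselective = 0.25))
  ses <- simulate_session(
    pop, n_trials_per_condition = c(singleton_present = 200,
                                    singleton_absent = 20, mixed_color = 20),
    seed = 15, window = c(-300, 300))
  w <- data.frame(start = 150, end = 200)
  lab_t <- label_trials(ses, "target_location")
  lab_s <- label_trials(ses, "singleton_location")
  called <- vapply(seq_along(ses$unit_ids), function(ui) {
    uid <- ses$unit_ids[ui]
    zt <- pev_omega2(sliding_counts(ses, uid, lab_t$trial_id, w),
                     lab_t$label, n_shuffle = 200, seed = ui)$z
    zs <- pev_omega2(sliding_counts(ses, uid, lab_s$trial_id, w),
                     lab_s$label, n_shuffle = 200, seed = ui + 999)$z
    classify_selectivity(zt, zs)
  }, character(1))
  planted <- pop$planted_classes
  # tuned units are overwhelmingly detected as tuned
  tuned <- planted != "nonselective"
  expect_gt(mean(called[tuned] != "nonselective"), 0.7)
  # nonselective units are rarely called mixed (double false positive)
  expect_lt(mean(called[!tuned] == "mixed"), 0.2)
  # singleton-only units are almost never called target-only and vice versa
  expect_lt(mean(called[planted == "singleton"] == "target"), 0.25)
  expect_lt(mean(called[planted == "target"] == "singleton"), 0.25)
})
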