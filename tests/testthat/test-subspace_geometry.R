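# deterministic low-rank covariance helpers
lowrank_cov <- function(n, support, values) {
  q <- diag(n)[, support, drop = FALSE]
  q %*% diag(values, length(support)) %*% t(q)
}

test_that("condition matrix has locations x time rows and centred columns", {
  fx <- fixture_session()
  m <- build_condition_matrix(fx$ses, "target")
  expect_equal(nrow(m), 5 * 51)            # 255 rows
  expect_equal(ncol(m), length(fx$ses$unit_ids))
  expect_lt(max(abs(colMeans(m))), 1e-10)

  # dropping every trial with the target at one location raises a named error
  ses2 <- fx$ses
  drop <- ses2$trials$display_type == "singleton_present" &
    ses2$trials$target_pos == 4
  ses2$trials <- ses2$trials[!drop, ]
  expect_error(build_condition_matrix(ses2, "target"), "position 4")
})

test_that("alignment index matches brute-force trace evaluation", {
  n <- 12; d <- 3
  c_mat <- with_seed_test(1, {
    a <- matrix(rnorm(n * n), n)
    crossprod(a) / n
  })
  ev <- eigen(c_mat, symmetric = TRUE)

  q_top <- ev$vectors[, 1:d]
  expect_equal(alignment_index(q_top, c_mat), 1, tolerance = 1e-10)

  c_rank_d <- ev$vectors[, 1:d] %*% diag(ev$values[1:d]) %*% t(ev$vectors[, 1:d])
  q_null <- ev$vectors[, (d + 1):(2 * d)]
  expect_equal(alignment_index(q_null, c_rank_d), 0, tolerance = 1e-10)

  for (r in 1:5) {
    q <- with_seed_test(10 + r, qr.Q(qr(matrix(rnorm(n * d), n))))
    brute <- sum(diag(t(q) %*% c_mat %*% q)) /
      sum(sort(eigen(c_mat, only.values = TRUE)$values, decreasing = TRUE)[1:d])
    expect_equal(alignment_index(q, c_mat), brute, tolerance = 1e-12)
  }
  expect_error(alignment_index(q_top, matrix(0, n, n)), "rank 0")
})

test_that("orthogonal pair recovers disjoint supports and the analytic optimum", {
  n <- 16; d <- 3
  cov <- structure(list(
    target = lowrank_cov(n, 1:3, c(5, 4, 3)),
    singleton = lowrank_cov(n, 6:8, c(6, 4, 2))), class = "covariance_pair")
  cov$eig <- list(
    target = sort(eigen(cov$target, only.values = TRUE)$values, decreasing = TRUE),
    singleton = sort(eigen(cov$singleton, only.values = TRUE)$values, decreasing = TRUE))
  fit <- fit_orthogonal_pair(cov, d = d, seed = 1)
  expect_gte(fit$alignment[["target_on_orth_target"]], 0.99)
  expect_gte(fit$alignment[["singleton_on_orth_singleton"]], 0.99)
  expect_lte(fit$alignment[["target_on_orth_singleton"]], 0.01)
  q <- cbind(fit$q_target, fit$q_singleton)
  expect_lt(max(abs(crossprod(q) - diag(2 * d))), 1e-8)

  # identical covariances of rank 2d: objective equals the analytic optimum
  vals <- c(8, 6, 5, 4, 3, 2)
  c_same <- lowrank_cov(n, 1:6, vals)
  cov2 <- structure(list(target = c_same, singleton = c_same,
                         eig = list(target = sort(vals, decreasing = TRUE),
                                    singleton = sort(vals, decreasing = TRUE))),
                    class = "covariance_pair")
  cov2$eig <- lapply(cov2$eig, function(e) c(e, rep(0, n - 6)))
  fit2 <- fit_orthogonal_pair(cov2, d = 3, seed = 2)
  analytic <- sum(vals) / sum(vals[1:3])
  expect_equal(fit2$objective, analytic, tolerance = 0.01)
})

test_that("d = 1 orthogonal pair matches exhaustive grid search at N = 3", {
  c_t <- with_seed_test(2, { a <- matrix(rnorm(9), 3); crossprod(a) })
  c_s <- with_seed_test(3, { a <- matrix(rnorm(9), 3); crossprod(a) })
  cov <- structure(list(
    target = c_t, singleton = c_s,
    eig = list(target = sort(eigen(c_t, only.values = TRUE)$values, decreasing = TRUE),
               singleton = sort(eigen(c_s, only.values = TRUE)$values, decreasing = TRUE))),
    class = "covariance_pair")
  fit <- fit_orthogonal_pair(cov, d = 1, seed = 1)

  # grid over q1 on the sphere and q2 on the orthogonal circle
  best <- -Inf
  for (az in seq(0, pi, length.out = 60)) for (el in seq(0, pi, length.out = 60)) {
    q1 <- c(cos(az) * sin(el), sin(az) * sin(el), cos(el))
    u <- c(-sin(az), cos(az), 0)
    v <- c(cos(az) * cos(el), sin(az) * cos(el), -sin(el))
    for (ph in seq(0, pi, length.out = 60)) {
      q2 <- cos(ph) * u + sin(ph) * v
      obj <- c(q1 %*% c_t %*% q1) / cov$eig$target[1] +
        c(q2 %*% c_s %*% q2) / cov$eig$singleton[1]
      if (obj > best) best <- obj
    }
  }
  expect_gte(fit$objective, best * 0.99)
  expect_lte(fit$objective, best * 1.01 + 0.01)
})

test_that("exclusive subspace honours its variance cap in all regimes", {
  n <- 16; d <- 3
  c_max <- lowrank_cov(n, 1:4, c(5, 4, 3, 2))
  # null limit covariance: reduces to the principal subspace
  fit0 <- fit_exclusive(c_max, matrix(0, n, n), d = d, seed = 1)
  expect_equal(fit0$alignment_max, 1, tolerance = 1e-8)
  expect_equal(fit0$alignment_limit, 0)

  # disjoint supports: constraint inactive
  c_lim <- lowrank_cov(n, 9:11, c(3, 2, 1))
  fit1 <- fit_exclusive(c_max, c_lim, d = d, seed = 1)
  expect_gte(fit1$alignment_max, 0.99)
  expect_lte(fit1$alignment_limit, 0.01 + 1e-4)

  # overlapping planted data: cap binds but is respected
  fx <- fixture_session()
  cov <- covariance_pair(build_condition_matrix(fx$ses, "target"),
                         build_condition_matrix(fx$ses, "singleton"))
  fit2 <- fit_exclusive(cov$target, cov$singleton, v = 0.01, d = 5, seed = 1)
  expect_lte(fit2$alignment_limit, 0.01 + 1e-4)
  expect_lt(max(abs(crossprod(fit2$q) - diag(5))), 1e-8)

  # full-rank isotropic limit: infeasible at v = 1e-3
  expect_error(fit_exclusive(c_max, diag(n), v = 1e-3, d = d),
               "infeasible")
})

test_that("shared subspace tracks the planted overlap and stays orthogonal", {
  sub_for_overlap <- function(ov, seed) {
    pop <- make_unit_population(40, geometry = geometry_spec(5, ov),
                                seed = seed)
    # positions x units noiseless pattern matrices
    covariance_pair(planted_condition_patterns(pop, "target"),
                    planted_condition_patterns(pop, "singleton"))
  }
  # d matches the planted dimensionality (5)
  cov1 <- sub_for_overlap(1, 4)
  ex_t <- fit_exclusive(cov1$target, cov1$singleton, d = 5, seed = 1)
  ex_s <- fit_exclusive(cov1$singleton, cov1$target, d = 5, seed = 1)
  sh1 <- fit_shared(cov1, ex_t$q, ex_s$q, d = 5)
  expect_gte(sh1$alignment[["target"]], 0.8)
  expect_gte(sh1$alignment[["singleton"]], 0.8)
  expect_lte(sh1$orthogonality_residual, 1e-6)

  cov0 <- sub_for_overlap(0, 5)
  ex_t0 <- fit_exclusive(cov0$target, cov0$singleton, d = 5, seed = 1)
  ex_s0 <- fit_exclusive(cov0$singleton, cov0$target, d = 5, seed = 1)
  sh0 <- fit_shared(cov0, ex_t0$q, ex_s0$q, d = 5)
  expect_lte(sh0$alignment[["target"]], 0.1)
  expect_lte(sh0$alignment[["singleton"]], 0.1)

  expect_error(fit_shared(cov0, diag(40)[, 1:19], diag(40)[, 20:38], d = 3),
               "smaller d")
})

test_that("optimiser objective is monotone and bases orthonormal to tolerance", {
  fx <- fixture_session()
  cov <- covariance_pair(build_condition_matrix(fx$ses, "target"),
                         build_condition_matrix(fx$ses, "singleton"))
  fit <- fit_orthogonal_pair(cov, d = 5, seed = 3)
  q <- cbind(fit$q_target, fit$q_singleton)
  expect_lt(max(abs(crossprod(q) - diag(10))), 1e-8)
  expect_true(all(fit$alignment >= 0 & fit$alignment <= 1 + 1e-10))

  obj <- function(qq) sum(diag(crossprod(qq, cov$target %*% qq)))
  tr <- stiefel_ascent(
    obj, function(qq) 2 * cov$target %*% qq,
    with_seed_test(6, qr.Q(qr(matrix(rnorm(length(fx$ses$unit_ids) * 3), ncol = 3)))),
    max_iter = 100)$trace
  expect_true(all(diff(tr) >= -1e-12))
})

test_that("unit weights satisfy the orthonormality identity", {
  q <- with_seed_test(7, qr.Q(qr(matrix(rnorm(30 * 4), 30))))
  w <- unit_weights(q)
  expect_equal(sum(w$weights^2), 4, tolerance = 1e-10)

  q_zero <- rbind(qr.Q(qr(matrix(rnorm(29 * 4), 29))), 0)
  expect_equal(unit_weights(q_zero)$weights[30], 0)

  cls <- rep(c("target", "singleton", "mixed", "nonselective"), length.out = 30)
  wa <- unit_weights(q, cls)
  expect_true(is.numeric(wa$anova$p) && wa$anova$p >= 0 && wa$anova$p <= 1)

  # equal-contribution null: ANOVA rarely significant
  ps <- vapply(1:20, function(i) {
    qi <- with_seed_test(100 + i, qr.Q(qr(matrix(rnorm(40 * 5), 40))))
    unit_weights(qi, rep(c("a", "b", "c", "d"), each = 10))$anova$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("projected decoding keeps same-context information, loses cross at overlap 0", {
  # bases from the planted (noiseless) covariances; decoding labels taken
  # from singleton-absent trials so singleton-span projections carry no
  # task-structure leakage (on singleton-present trials the singleton
  # position itself weakly predicts the target position)
  w <- data.frame(start = 150, end = 200)
  setup <- function(ov, pop_seed, ses_seed) {
    pop <- make_unit_population(40, geometry = geometry_spec(5, ov),
                                seed = pop_seed)
    ses <- simulate_session(
      pop, n_trials_per_condition = c(singleton_present = 50,
                                      singleton_absent = 150,
                                      mixed_color = 15),
      seed = ses_seed, window = c(0, 260))
    cov <- covariance_pair(planted_condition_patterns(pop, "target"),
                           planted_condition_patterns(pop, "singleton"))
    fit <- fit_orthogonal_pair(cov, d = 5, seed = 1)
    tr <- ses$trials
    keep <- tr$display_type == "singleton_absent" &
      tr$target_pos %in% left_hemifield_positions()
    labels <- list(data.frame(trial_id = tr$trial_id[keep],
                              label = factor(tr$target_pos[keep])))
    pp <- build_pseudopopulation(ses, labels, n_trials = 10,
                                 n_resamples = 4, seed = 2, windows = w)
    list(fit = fit, pp = pp)
  }

  s0 <- setup(0, 8, 9)
  same <- projected_decoding(s0$pp, s0$fit$q_target, seed = 3)
  expect_gte(mean(same$accuracy), 0.7)

  cross <- projected_decoding(s0$pp, s0$fit$q_singleton, seed = 4)
  accs <- as.vector(cross$accuracy)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.2), 3 * se + 0.05)

  # partial overlap: cross-projected activity decodes above chance
  s5 <- setup(0.5, 18, 19)
  cross5 <- projected_decoding(s5$pp, s5$fit$q_singleton, seed = 4)
  expect_gt(mean(cross5$accuracy), 0.25)

  expect_error(projected_decoding(s0$pp, s0$fit$q_target[1:10, ]), "units")
})
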