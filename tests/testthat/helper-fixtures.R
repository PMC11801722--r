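# shared fixtures, built once per test run and memoised

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# mid-sized mixed-archetype session used by several modules
fixture_session <- function() memo("session_main", function() {
  pop <- make_unit_population(50, geometry = geometry_spec(5, 0.5), seed = 101)
  ses <- simulate_session(
    pop, n_trials_per_condition = c(singleton_present = 150,
                                    singleton_absent = 40, mixed_color = 40),
    seed = 102, window = c(-300, 300))
  list(pop = pop, ses = ses)
})

# all-suppression session for sign checks and behaviour coupling
fixture_suppression_session <- function() memo("session_supp", function() {
  pop <- make_unit_population(20, cluster_mix = c(suppression = 1), seed = 201)
  ses <- simulate_session(
    pop, n_trials_per_condition = c(singleton_present = 320,
                                    singleton_absent = 30, mixed_color = 30),
    seed = 202, window = c(-300, 300))
  list(pop = pop, ses = ses)
})

# three-archetype t-profile blobs with planted labels
archetype_blobs <- function(n_per = 50, noise_sd = 1, seed = 1) {
  tgrid <- 0:299
  templates <- sapply(c("suppression", "early_enh_late_supp", "enhancement"),
                      function(a) (archetype_gain(a, tgrid) - 1) * 10)
  labels <- rep(1:3, each = n_per)
  x <- with_seed_test(seed, t(sapply(labels, function(l)
    templates[, l] + rnorm(length(tgrid), 0, noise_sd))))
  list(x = x, labels = labels)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# exhaustive pairwise AUROC oracle: P(a > b) + 0.5 P(a == b)
auroc_enumeration <- function(a, b)
  mean(outer(a, b, ">") + 0.5 * outer(a, b, "=="))

# omega^2 oracle from a direct ANOVA decomposition via stats::anova
omega2_anova_oracle <- function(y, g) {
  fit <- stats::anova(stats::lm(y ~ factor(g)))
  ssb <- fit$`Sum Sq`[1]
  sse <- fit$`Sum Sq`[2]
  dfb <- fit$Df[1]
  mse <- fit$`Mean Sq`[2]
  (ssb - dfb * mse) / (ssb + sse + mse)
}

# rank-based adjusted Rand index oracle comes from mclust (Suggests)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# minimal session stub carrying only trial metadata
trials_only_session <- function(trials) {
  structure(list(trials = trials, unit_ids = character(0)),
            class = "search_session")
}
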