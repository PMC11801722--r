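#' Build a location-by-time condition matrix
#'
#' Stacks per-location mean smoothed firing rates over the subspace window
#' (150-200 ms after array onset inclusive, 51 points on the 1-ms grid) into
#' a (locations x time) x units matrix, then removes each unit's mean across
#' rows. With the default five contralateral locations the matrix has
#' 255 rows.
#'
#' @param session a `search_session`.
#' @param context `"target"` or `"singleton"`: which factor's location
#'   defines the conditions (singleton-present displays).
#' @param positions 0-based location set.
#' @param window ms window `c(first, last)`, inclusive, 1-ms grid.
#' @param kernel a [kernel_params()].
#' @return matrix of class `condition_matrix` with attributes `context`,
#'   `positions`, `time`.
#' @export
build_condition_matrix <- function(session,
                                   context = c("target", "singleton"),
                                   positions = left_hemifield_positions(session$layout),
                                   window = c(150, 200),
                                   kernel = kernel_params()) {
  context <- match.arg(context)
  tr <- session$trials
  pos <- if (context == "target") tr$target_pos else tr$singleton_pos
  keep <- tr$display_type == "singleton_present" & !is.na(pos)
  grid <- seq(window[1], window[2])
  blocks <- lapply(positions, function(p) {
    ids <- tr$trial_id[keep & pos == p]
    if (length(ids) == 0)
      stop("no singleton-present trials with ", context, " at position ", p)
    vapply(session$unit_ids, function(uid) {
      colMeans(rate_matrix(session, uid, ids, c(window[1], window[2] + 1),
                           kernel))
    }, numeric(length(grid)))
  })
  x <- do.call(rbind, blocks)
  x <- sweep(x, 2, colMeans(x))
  structure(x, class = c("condition_matrix", "matrix"),
            context = context, positions = positions, time = grid)
}

#' Covariance pair for the two location contexts
#'
#' @param mat_target,mat_singleton row-centred condition matrices
#'   (rows = conditions x time, columns = units).
#' @return object of class `covariance_pair`: list with `target`,
#'   `singleton` (N x N covariance matrices) and `eig` (sorted eigenvalues
#'   per context).
#' @export
covariance_pair <- function(mat_target, mat_singleton) {
  stopifnot(ncol(mat_target) == ncol(mat_singleton))
  cv <- function(x) crossprod(as.matrix(x)) / (nrow(x) - 1)
  ct <- cv(mat_target)
  cs <- cv(mat_singleton)
  structure(list(
    target = ct, singleton = cs,
    eig = list(target = sort(eigen(ct, symmetric = TRUE, only.values = TRUE)$values,
                             decreasing = TRUE),
               singleton = sort(eigen(cs, symmetric = TRUE, only.values = TRUE)$values,
                                decreasing = TRUE))
  ), class = "covariance_pair")
}

#' Alignment index of a subspace with a covariance
#'
#' `A = Tr(Q' C Q) / sum_{i<=d} lambda_i`, the variance of activity captured
#' by the d-dimensional orthonormal basis `Q` normalised by the maximum
#' variance any d-dimensional subspace can capture (the top-d eigenvalue
#' sum); lies in \[0, 1\].
#'
#' @param q orthonormal N x d basis.
#' @param c_mat N x N covariance matrix.
#' @param d normalising dimension (default `ncol(q)`).
#' @return scalar alignment index.
#' @export
alignment_index <- function(q, c_mat, d = ncol(q)) {
  ev <- sort(eigen(c_mat, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  denom <- sum(ev[seq_len(d)])
  if (denom <= 0) stop("covariance has rank 0: alignment undefined")
  sum(diag(crossprod(q, c_mat %*% q))) / denom
}

# ---- Stiefel-manifold gradient ascent -------------------------------------

sym_part <- function(a) (a + t(a)) / 2

# QR retraction with sign-fixed R diagonal (deterministic)
stiefel_retract <- function(y) {
  qr_ <- qr(y)
  q <- qr.Q(qr_)
  r <- qr.R(qr_)
  s <- sign(diag(r))
  s[s == 0] <- 1
  q %*% diag(s, ncol(q))
}

# project ambient gradient onto the tangent space at q
stiefel_project <- function(q, g) g - q %*% sym_part(crossprod(q, g))

#' Riemannian gradient ascent on the Stiefel manifold
#'
#' Maximises a smooth objective over orthonormal N x p frames using
#' projected-gradient ascent with QR retraction and Armijo backtracking.
#' The objective is non-decreasing over iterations; convergence is declared
#' when the Riemannian gradient norm falls below `tol`.
#'
#' @param obj_fn objective `f(Q)` to maximise.
#' @param grad_fn ambient (Euclidean) gradient of `f`.
#' @param q0 orthonormal starting frame.
#' @param max_iter iteration budget.
#' @param tol gradient-norm tolerance.
#' @return list with `q`, `objective`, `grad_norm`, `converged`,
#'   `iterations`, `trace` (objective per iteration).
#' @export
stiefel_ascent <- function(obj_fn, grad_fn, q0, max_iter = 500, tol = 1e-6) {
  q <- q0
  f <- obj_fn(q)
  trace <- f
  step <- 1
  for (it in seq_len(max_iter)) {
    g <- stiefel_project(q, grad_fn(q))
    gn <- sqrt(sum(g^2))
    if (gn <= tol) {
      return(list(q = q, objective = f, grad_norm = gn, converged = TRUE,
                  iterations = it - 1L, trace = trace))
    }
    step <- min(step * 2, 1 / max(gn, 1e-12))
    accepted <- FALSE
    for (ls in 1:40) {
      q_new <- stiefel_retract(q + step * g)
      f_new <- obj_fn(q_new)
      if (f_new >= f + 1e-4 * step * gn^2) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) {
      return(list(q = q, objective = f, grad_norm = gn, converged = TRUE,
                  iterations = it, trace = trace))
    }
    q <- q_new
    f <- f_new
    trace <- c(trace, f)
  }
  g <- stiefel_project(q, grad_fn(q))
  list(q = q, objective = f, grad_norm = sqrt(sum(g^2)), converged = FALSE,
       iterations = max_iter, trace = trace)
}

top_eigvectors <- function(c_mat, d) {
  eigen(c_mat, symmetric = TRUE)$vectors[, seq_len(d), drop = FALSE]
}

# random orthonormal N x p frame from the current RNG
random_frame <- function(n, p) stiefel_retract(matrix(rnorm(n * p), n, p))

#' Fit mutually orthogonal target and singleton subspaces
#'
#' Jointly optimises an orthonormal N x 2d frame whose first d columns
#' capture target-location variance and last d columns capture
#' singleton-location variance, maximising the sum of the two normalised
#' captured variances; mutual orthogonality of the two blocks is enforced by
#' the frame constraint itself. Initialised from the principal components of
#' each covariance plus random restarts; the best objective is kept.
#'
#' @param cov a [covariance_pair()].
#' @param d subspace dimension.
#' @param n_restarts random restarts in addition to the PC initialisation.
#' @param seed integer seed.
#' @param max_iter,tol optimiser controls.
#' @return object of class `subspace_fit`: list with `q_target`,
#'   `q_singleton`, `objective`, `alignment` (named: each basis against each
#'   context), `optim` (convergence info).
#' @export
fit_orthogonal_pair <- function(cov, d = 5L, n_restarts = 5L, seed = 1L,
                                max_iter = 500, tol = 1e-6) {
  n <- nrow(cov$target)
  if (n < 2 * d) stop("need at least 2d units")
  st <- sum(cov$eig$target[seq_len(d)])
  ss <- sum(cov$eig$singleton[seq_len(d)])
  obj <- function(q) {
    q1 <- q[, seq_len(d), drop = FALSE]
    q2 <- q[, d + seq_len(d), drop = FALSE]
    sum(diag(crossprod(q1, cov$target %*% q1))) / st +
      sum(diag(crossprod(q2, cov$singleton %*% q2))) / ss
  }
  grad <- function(q) {
    q1 <- q[, seq_len(d), drop = FALSE]
    q2 <- q[, d + seq_len(d), drop = FALSE]
    cbind(2 * (cov$target %*% q1) / st, 2 * (cov$singleton %*% q2) / ss)
  }
  inits <- with_seed(child_seed(seed, 13L), {
    pc_t <- top_eigvectors(cov$target, d)
    pc_s <- top_eigvectors(cov$singleton, d)
    pc_s <- pc_s - pc_t %*% crossprod(pc_t, pc_s)
    init0 <- stiefel_retract(cbind(pc_t, pc_s))
    c(list(init0), lapply(seq_len(n_restarts), function(i) random_frame(n, 2 * d)))
  })
  fits <- lapply(inits, function(q0)
    stiefel_ascent(obj, grad, q0, max_iter = max_iter, tol = tol))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "objective"))]]
  q1 <- best$q[, seq_len(d), drop = FALSE]
  q2 <- best$q[, d + seq_len(d), drop = FALSE]
  structure(list(
    q_target = q1, q_singleton = q2, objective = best$objective,
    alignment = c(
      target_on_orth_target = alignment_index(q1, cov$target, d),
      singleton_on_orth_singleton = alignment_index(q2, cov$singleton, d),
      target_on_orth_singleton = alignment_index(q2, cov$target, d),
      singleton_on_orth_target = alignment_index(q1, cov$singleton, d)),
    optim = best[c("grad_norm", "converged", "iterations")]
  ), class = "subspace_fit")
}

#' Fit an exclusive subspace
#'
#' Maximises the normalised variance captured for one context while keeping
#' the normalised variance captured for the other context below `v`
#' (default 0.01, i.e. 1%). The constraint is handled by an exterior
#' quadratic penalty with continuation (the penalty weight is raised until
#' the returned point satisfies the constraint to within `constraint_tol`);
#' feasibility is verified post hoc.
#'
#' @param cov_max covariance whose variance is maximised.
#' @param cov_limit covariance whose captured variance is capped.
#' @param v variance cap for the limit context.
#' @param d subspace dimension.
#' @param seed integer seed (random restarts).
#' @param n_restarts random restarts in addition to the PC initialisation.
#' @param constraint_tol allowed excess over `v` at the returned point.
#' @param max_iter,tol optimiser controls.
#' @return list with `q`, `alignment_max`, `alignment_limit`, `optim`.
#' @export
fit_exclusive <- function(cov_max, cov_limit, v = 0.01, d = 5L, seed = 1L,
                          n_restarts = 2L, constraint_tol = 1e-4,
                          max_iter = 500, tol = 1e-6) {
  n <- nrow(cov_max)
  if (n < d) stop("need at least d units")
  ev_max <- sort(eigen(cov_max, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
  ev_lim <- sort(eigen(cov_limit, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
  s_max <- sum(ev_max[seq_len(d)])
  s_lim <- sum(ev_lim[seq_len(d)])
  if (s_lim <= 0) {
    # limit covariance is null: unconstrained principal subspace
    q <- top_eigvectors(cov_max, d)
    return(list(q = q, alignment_max = alignment_index(q, cov_max, d),
                alignment_limit = 0,
                optim = list(converged = TRUE, iterations = 0L,
                             grad_norm = 0)))
  }
  min_lim <- sum(sort(ev_lim)[seq_len(d)]) / s_lim
  if (min_lim > v + constraint_tol)
    stop(sprintf(
      "infeasible: minimal achievable limit-context variance is %.4g > v = %.4g",
      min_lim, v))

  a_max <- function(q) sum(diag(crossprod(q, cov_max %*% q))) / s_max
  a_lim <- function(q) sum(diag(crossprod(q, cov_limit %*% q))) / s_lim

  run_penalty <- function(q0) {
    q <- q0
    for (mu in 10^(2:8)) {
      obj <- function(q) {
        excess <- max(0, a_lim(q) - v)
        a_max(q) - mu * excess^2
      }
      grad <- function(q) {
        excess <- max(0, a_lim(q) - v)
        2 * (cov_max %*% q) / s_max -
          mu * 2 * excess * 2 * (cov_limit %*% q) / s_lim
      }
      fit <- stiefel_ascent(obj, grad, q, max_iter = max_iter, tol = tol)
      q <- fit$q
      if (a_lim(q) <= v + constraint_tol / 2) break
    }
    list(q = q, fit = fit)
  }

  inits <- with_seed(child_seed(seed, 14L), {
    # start from the principal subspace of the max context with the limit
    # directions deflated
    q0 <- top_eigvectors(cov_max - cov_limit * (s_max / s_lim), d)
    c(list(q0), lapply(seq_len(n_restarts), function(i) random_frame(n, d)))
  })
  runs <- lapply(inits, run_penalty)
  feas <- vapply(runs, function(r) a_lim(r$q) <= v + constraint_tol, logical(1))
  score <- vapply(runs, function(r) a_max(r$q), numeric(1))
  score[!feas] <- -Inf
  if (all(!feas))
    stop("exclusive-subspace optimisation failed to satisfy the variance cap")
  best <- runs[[which.max(score)]]
  list(q = best$q,
       alignment_max = a_max(best$q),
       alignment_limit = a_lim(best$q),
       optim = best$fit[c("grad_norm", "converged", "iterations")])
}

#' Fit the shared subspace
#'
#' Finds the d-dimensional basis orthogonal to both exclusive subspaces that
#' jointly maximises the normalised target and singleton variance. Within
#' the orthogonal complement the objective is a single quadratic trace, so
#' the optimum is computed exactly from the top-d eigenvectors of the
#' complement-projected sum of normalised covariances.
#'
#' @param cov a [covariance_pair()].
#' @param q_excl_target,q_excl_singleton exclusive bases from
#'   [fit_exclusive()].
#' @param d subspace dimension.
#' @return list with `q`, `alignment` (named, per context), and
#'   `orthogonality_residual`.
#' @export
fit_shared <- function(cov, q_excl_target, q_excl_singleton, d = 5L) {
  n <- nrow(cov$target)
  excl <- cbind(q_excl_target, q_excl_singleton)
  qe <- qr(excl)
  comp_dim <- n - qe$rank
  if (comp_dim < d)
    stop("orthogonal complement has dimension ", comp_dim,
         " < d; use a smaller d")
  b <- qr.Q(qe, complete = TRUE)[, (qe$rank + 1):n, drop = FALSE]
  st <- sum(cov$eig$target[seq_len(d)])
  ss <- sum(cov$eig$singleton[seq_len(d)])
  m <- crossprod(b, (cov$target / st + cov$singleton / ss) %*% b)
  q <- b %*% top_eigvectors(sym_part(m), d)
  res <- max(abs(crossprod(q, excl)))
  list(q = q,
       alignment = c(target = alignment_index(q, cov$target, d),
                     singleton = alignment_index(q, cov$singleton, d)),
       orthogonality_residual = res)
}

#' Decode location from activity projected onto a subspace
#'
#' Projects the pseudo-population counts of each resample and window onto
#' the columns of `q` and decodes the labels from the d-dimensional
#' projections with the standard cross-validated linear SVM.
#'
#' @param pop a [build_pseudopopulation()] result whose unit dimension
#'   matches `nrow(q)`.
#' @param q orthonormal N x d basis.
#' @param ... passed to [decode_timecourse()].
#' @return a `decoding_result`.
#' @export
projected_decoding <- function(pop, q, ...) {
  n_units <- dim(pop$counts[[1]])[1]
  if (nrow(q) != n_units)
    stop("basis has ", nrow(q), " rows but the population has ", n_units,
         " units")
  proj <- pop
  proj$counts <- lapply(pop$counts, function(arr) {
    out <- array(0, dim = c(ncol(q), dim(arr)[2], dim(arr)[3]))
    for (w in seq_len(dim(arr)[3]))
      out[, , w] <- crossprod(q, arr[, , w])
    out
  })
  decode_timecourse(proj, ...)
}

#' Per-unit subspace weights
#'
#' A unit's contribution to a subspace is the Euclidean norm of its row of
#' `Q`; squared row norms sum to d. When selectivity classes are supplied,
#' the weights are compared across classes with a one-way ANOVA.
#'
#' @param q orthonormal N x d basis.
#' @param classes optional per-unit selectivity class
#'   (target/singleton/mixed/nonselective).
#' @return list with `weights` and, given `classes`, `anova` (`F`, `df`,
#'   `p`).
#' @export
unit_weights <- function(q, classes = NULL) {
  w <- sqrt(rowSums(q^2))
  out <- list(weights = w)
  if (!is.null(classes)) {
    classes <- droplevels(as.factor(classes))
    if (nlevels(classes) >= 2) {
      fit <- stats::anova(stats::lm(w ~ classes))
      out$anova <- list(F = fit$`F value`[1], df = fit$Df, p = fit$`Pr(>F)`[1])
    }
  }
  out
}
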