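#' Search-array task layout
#'
#' Describes the 8-stimulus search array: positions are arranged on a rhombus
#' at indices 0-7, index 0 at the right horizontal meridian, counted
#' counterclockwise. Index 4 is therefore the left horizontal position and
#' indices 2 and 6 the two vertical-meridian positions. One unit population is
#' simulated with a common receptive-field (RF) location.
#'
#' @param n_positions number of array positions (8).
#' @param rf_position 0-based index of the simulated RF location.
#' @param eccentricity_deg array eccentricity in degrees of visual angle.
#' @return an object of class `task_layout`.
#' @export
task_layout <- function(n_positions = 8L, rf_position = 4L, eccentricity_deg = 6) {
  n_positions <- as.integer(n_positions)
  rf_position <- as.integer(rf_position)
  if (n_positions < 2L) stop("`n_positions` must be at least 2")
  if (rf_position < 0L || rf_position >= n_positions)
    stop("`rf_position` must be in 0..", n_positions - 1L)
  structure(list(
    n_positions = n_positions,
    angles_deg = (seq_len(n_positions) - 1L) * 360 / n_positions,
    rf_position = rf_position,
    eccentricity_deg = eccentricity_deg
  ), class = "task_layout")
}

#' Contralateral (left-hemifield) location set
#'
#' The five positions used for location decoding and subspace analysis: the
#' three left-hemifield positions plus the two vertical-meridian positions.
#'
#' @param layout a [task_layout()].
#' @return integer vector of 0-based position indices.
#' @export
left_hemifield_positions <- function(layout = task_layout()) {
  ang <- layout$angles_deg
  sort(which(ang >= 90 & ang <= 270) - 1L)
}

#' Planted population-geometry specification
#'
#' Controls the ground-truth geometry of target-location and
#' singleton-location population patterns. `overlap` maps to planted
#' principal angles between the two tuning subspaces via
#' `theta = acos(sqrt(overlap))`, so the shared variance fraction between the
#' two pattern sets equals `overlap`: 0 plants fully orthogonal subspaces
#' (all principal angles 90 degrees), 1 plants identical subspaces.
#'
#' @param d_true planted dimensionality, between 1 and 5.
#' @param overlap scalar in \[0, 1\].
#' @return an object of class `geometry_spec`.
#' @export
geometry_spec <- function(d_true = 5L, overlap = 0.5) {
  d_true <- as.integer(d_true)
  if (d_true < 1L || d_true > 5L) stop("`d_true` must be between 1 and 5")
  if (!is.numeric(overlap) || overlap < 0 || overlap > 1)
    stop("`overlap` must lie in [0, 1]")
  structure(list(d_true = d_true, overlap = overlap), class = "geometry_spec")
}

#' Planted principal angle implied by an overlap value
#'
#' @param overlap scalar in \[0, 1\].
#' @return angle in degrees.
#' @export
overlap_to_angle <- function(overlap) acos(sqrt(pmin(pmax(overlap, 0), 1))) * 180 / pi

#' Principal angles between two subspaces
#'
#' @param a,b matrices whose column spans are compared (need not be
#'   orthonormal; they are orthonormalised internally).
#' @return vector of principal angles in degrees, ascending.
#' @export
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(a))[, seq_len(qr(a)$rank), drop = FALSE]
  qb <- qr.Q(qr(b))[, seq_len(qr(b)$rank), drop = FALSE]
  s <- svd(crossprod(qa, qb))$d
  sort(acos(pmin(pmax(s, -1), 1)) * 180 / pi)
}

# orthonormal basis pair (U, V) with principal angles theta (cos theta = c)
planted_basis_pair <- function(n_units, d, overlap) {
  if (n_units < 2 * d) stop("need at least 2*d_true units to plant the geometry")
  u <- qr.Q(qr(matrix(rnorm(n_units * d), n_units, d)))
  w <- matrix(rnorm(n_units * d), n_units, d)
  w <- w - u %*% crossprod(u, w)           # complement of u
  w <- qr.Q(qr(w))
  ct <- sqrt(overlap)
  st <- sqrt(1 - overlap)
  list(target = u, singleton = u * ct + w * st)
}

#' Temporal gain profile of a selectivity archetype
#'
#' Multiplicative gain applied to the RF-stimulus response when the colour
#' singleton falls inside the RF, on a 1-ms grid. Gains equal 1 outside
#' \[0, 300\] ms for every archetype. Shapes (defaults): `suppression` dips
#' below 1 from 60 ms; `early_enh_late_supp` rises above 1 over \[25, 100) ms
#' then falls below 1 over \[125, 300) ms; `enhancement` rises above 1 from
#' 85 ms; `nonselective` stays at 1.
#'
#' @param cluster_id one of `"suppression"`, `"early_enh_late_supp"`,
#'   `"enhancement"`, `"nonselective"`.
#' @param t time in ms relative to array onset (vector).
#' @param depth peak deviation from 1 (suppression dips to `1 - depth`,
#'   enhancement rises to `1 + depth`).
#' @return numeric gain vector, same length as `t`.
#' @export
archetype_gain <- function(cluster_id, t, depth = 0.3) {
  ramp <- function(t, t0, t1) pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  g <- rep(1, length(t))
  if (cluster_id == "suppression") {
    # down from 60 ms, sustained, released by 300 ms
    g <- 1 - depth * ramp(t, 60, 90) * (1 - ramp(t, 285, 300))
  } else if (cluster_id == "early_enh_late_supp") {
    up <- depth * ramp(t, 25, 40) * (1 - ramp(t, 85, 100))
    dn <- (depth * 0.85) * ramp(t, 125, 150) * (1 - ramp(t, 285, 300))
    g <- 1 + up - dn
  } else if (cluster_id == "enhancement") {
    g <- 1 + depth * ramp(t, 85, 110) * (1 - ramp(t, 285, 300))
  } else if (cluster_id != "nonselective") {
    stop("unknown archetype: ", cluster_id)
  }
  g[t < 0 | t > 300] <- 1
  g
}

#' Generate a population of unit archetypes with planted ground truth
#'
#' Draws `n_units` archetypes from `cluster_mix`, assigns baseline rates and
#' visual gains, and constructs target- and singleton-location tuning vectors
#' whose population pattern matrices span planted subspaces with principal
#' angles set by `geometry$overlap` (see [geometry_spec()]).
#'
#' Optionally, `selectivity_mix` assigns each unit a planted spatial
#' selectivity class; units in the `target` class have their singleton-location
#' tuning zeroed (and vice versa), and `nonselective` units carry no location
#' tuning. Masking rows in this way makes the planted principal angles
#' approximate rather than exact, so leave `selectivity_mix = NULL` (all units
#' tuned to both factors) for subspace-geometry studies.
#'
#' @param n_units number of units (>= 1).
#' @param cluster_mix named proportions over the four archetypes; must sum
#'   to 1.
#' @param geometry a [geometry_spec()].
#' @param seed integer seed; all randomness in the population derives from it.
#' @param baseline_range range of baseline rates, spikes/s.
#' @param visual_gain_range range of multiplicative visual response gains.
#' @param tuning_sd standard deviation of per-unit location-tuning weights.
#' @param rate_scale spikes/s contributed by one unit of tuning weight.
#' @param selectivity_mix optional named proportions over
#'   `c("target", "singleton", "mixed", "nonselective")`.
#' @return an object of class `unit_population`: a list of archetypes plus the
#'   planted bases (`bases$target`, `bases$singleton`), the tuning matrices
#'   (`tuning_target`, `tuning_singleton`, units x positions), and the
#'   configuration used.
#' @export
make_unit_population <- function(n_units,
                                 cluster_mix = c(suppression = 0.35,
                                                 early_enh_late_supp = 0.2,
                                                 enhancement = 0.15,
                                                 nonselective = 0.3),
                                 geometry = geometry_spec(),
                                 seed = 1L,
                                 baseline_range = c(20, 40),
                                 visual_gain_range = c(2.5, 3.5),
                                 tuning_sd = 0.5,
                                 rate_scale = 40,
                                 selectivity_mix = NULL) {
  n_units <- as.integer(n_units)
  if (n_units < 1L) stop("`n_units` must be >= 1")
  valid <- c("suppression", "early_enh_late_supp", "enhancement", "nonselective")
  if (is.null(names(cluster_mix)) || !all(names(cluster_mix) %in% valid))
    stop("`cluster_mix` must be named with archetype ids")
  if (any(cluster_mix < 0) || abs(sum(cluster_mix) - 1) > 1e-9)
    stop("invalid `cluster_mix`: proportions must be non-negative and sum to 1")
  if (!inherits(geometry, "geometry_spec")) stop("`geometry` must be a geometry_spec")

  n_pos <- 8L
  with_seed(child_seed(seed, 1L), {
    ids <- sample(rep(names(cluster_mix),
                      diff(round(cumsum(c(0, cluster_mix)) * n_units))))
    # rounding can drop/add a unit at the margins; pad deterministically
    if (length(ids) < n_units)
      ids <- c(ids, rep(names(which.max(cluster_mix)), n_units - length(ids)))
    ids <- ids[seq_len(n_units)]

    baseline <- runif(n_units, baseline_range[1], baseline_range[2])
    vgain <- runif(n_units, visual_gain_range[1], visual_gain_range[2])

    bases <- planted_basis_pair(n_units, geometry$d_true, geometry$overlap)
    # location coefficients: centred across positions (so row-centering the
    # condition matrix leaves the planted span untouched) and isotropic
    # within the planted span (equal variance in every span direction, so
    # the planted cross-projected variance equals `overlap` exactly)
    coef_mat <- function() {
      m <- matrix(rnorm(n_pos * geometry$d_true), n_pos, geometry$d_true)
      m <- sweep(m, 2, colMeans(m))
      t(qr.Q(qr(m)))
    }
    w_t <- bases$target %*% coef_mat()
    w_s <- bases$singleton %*% coef_mat()
    w_t <- w_t * (tuning_sd / sd(w_t))
    w_s <- w_s * (tuning_sd / sd(w_s))

    sel_class <- rep("mixed", n_units)
    if (!is.null(selectivity_mix)) {
      cls <- c("target", "singleton", "mixed", "nonselective")
      if (is.null(names(selectivity_mix)) || !all(names(selectivity_mix) %in% cls) ||
          abs(sum(selectivity_mix) - 1) > 1e-9)
        stop("invalid `selectivity_mix`")
      sel_class <- sample(cls, n_units, replace = TRUE,
                          prob = selectivity_mix[match(cls, names(selectivity_mix))])
      w_s[sel_class %in% c("target", "nonselective"), ] <- 0
      w_t[sel_class %in% c("singleton", "nonselective"), ] <- 0
    }

    archetypes <- lapply(seq_len(n_units), function(i) {
      structure(list(
        unit_id = i,
        cluster_id = ids[i],
        baseline_rate = baseline[i],
        visual_gain = vgain[i],
        location_tuning = list(target = w_t[i, ], singleton = w_s[i, ]),
        planted_class = sel_class[i]
      ), class = "unit_archetype")
    })

    structure(list(
      archetypes = archetypes,
      n_units = n_units,
      cluster_ids = ids,
      planted_classes = sel_class,
      baseline = baseline,
      visual_gain = vgain,
      tuning_target = w_t,
      tuning_singleton = w_s,
      bases = bases,
      geometry = geometry,
      rate_scale = rate_scale,
      tuning_sd = tuning_sd,
      seed = seed
    ), class = "unit_population")
  })
}

#' @export
print.unit_population <- function(x, ...) {
  cat("unit_population:", x$n_units, "units\n")
  print(table(x$cluster_ids))
  cat("planted d =", x$geometry$d_true, " overlap =", x$geometry$overlap, "\n")
  invisible(x)
}

#' Noiseless planted condition patterns
#'
#' Mean response deviation (spikes/s) of each unit for each array position,
#' for the target or the singleton factor, exactly as injected by the rate
#' model of [simulate_session()] before Poisson noise. Rows are positions,
#' columns units. Used to verify planted geometry against recovered geometry.
#'
#' @param population a [make_unit_population()] result.
#' @param context `"target"` or `"singleton"`.
#' @param positions 0-based position indices (rows).
#' @return positions x units matrix.
#' @export
planted_condition_patterns <- function(population,
                                       context = c("target", "singleton"),
                                       positions = 0:7) {
  context <- match.arg(context)
  w <- if (context == "target") population$tuning_target else population$tuning_singleton
  t(w[, positions + 1L, drop = FALSE]) * population$rate_scale
}
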