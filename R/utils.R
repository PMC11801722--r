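#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions do not perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stream-specific child seed; kept below 2^31
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream) %% 2147483647
}

#' Half-open window membership on a time grid
#' @keywords internal
in_window <- function(t, window) t >= window[1] & t < window[2]

# runs of TRUE in a logical vector: data.frame(start, end, length) of indices
logical_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

# two-sided permutation/shuffle p-value with add-one correction
perm_pvalue <- function(observed, null, two_sided = TRUE) {
  n <- length(null)
  p_hi <- (sum(null >= observed) + 1) / (n + 1)
  p_lo <- (sum(null <= observed) + 1) / (n + 1)
  if (two_sided) min(1, 2 * min(p_hi, p_lo)) else p_hi
}
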