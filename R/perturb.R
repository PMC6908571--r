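#' Shuffle conditions independently for each neuron
#'
#' Surrogate-data operator: permutes the condition axis separately and
#' independently for every neuron, destroying condition-specific
#' correlations between neurons while preserving each neuron's multiset of
#' condition PETHs (and hence its across-condition average exactly).
#'
#' @param pop a `population_peth` with at least 2 conditions.
#' @param seed integer seed; the shuffle is deterministic given the seed.
#' @return A `population_peth` of the same shape; the applied permutations
#'   are attached as attribute `"permutations"` (one row per neuron, such
#'   that output condition `c` of neuron `i` is input condition
#'   `permutations[i, c]`).
#' @export
shuffle_conditions <- function(pop, seed = 1L) {
  stopifnot(inherits(pop, "population_peth"))
  d <- dim(pop$rates)
  if (d[2] < 2L) return(pop)
  perms <- with_seed(seed, {
    t(vapply(seq_len(d[1]), function(i) sample.int(d[2]), integer(d[2])))
  })
  rates <- pop$rates
  for (i in seq_len(d[1])) rates[i, , ] <- pop$rates[i, perms[i, ], ]
  out <- population_peth(rates, pop$grid, pop$neuron_ids, pop$condition_ids,
                         raw = pop$raw)
  attr(out, "permutations") <- perms
  out
}

#' Shift a block of conditions forward in time
#'
#' For the designated conditions, every neuron's PETH is delayed by
#' `shift_ms` (rightward on the time axis): the sample at time `t` becomes
#' the original sample at `t - shift_ms`, the initial `shift_ms` of each
#' PETH is filled with that PETH's original first sample, and samples pushed
#' beyond the window are dropped. All other conditions are untouched. This
#' emulates a block of conditions in which movement initiation is delayed,
#' and is the manipulation that restores enough across-condition
#' variability for the skew-symmetric fit to work on otherwise
#' ill-conditioned data.
#'
#' @param pop a `population_peth`.
#' @param shift_ms positive multiple of the grid step (default 100 ms).
#' @param conditions indices of conditions to shift; default the second half
#'   of the condition axis.
#' @return A `population_peth` of the same shape.
#' @export
shift_half <- function(pop, shift_ms = 100, conditions = NULL) {
  stopifnot(inherits(pop, "population_peth"))
  step <- pop$grid$step
  k <- shift_ms / step
  if (shift_ms <= 0 || abs(k - round(k)) > 1e-9)
    stop("'shift_ms' must be a positive multiple of the grid step (",
         step, " ms)")
  k <- as.integer(round(k))
  d <- dim(pop$rates)
  if (is.null(conditions))
    conditions <- seq.int(d[2] %/% 2 + 1L, d[2])
  if (any(conditions < 1L | conditions > d[2]))
    stop("'conditions' out of range")
  n_t <- d[3]
  if (k >= n_t) stop("'shift_ms' exceeds the time window")
  rates <- pop$rates
  first <- pop$rates[, conditions, 1, drop = FALSE]   # per-(neuron, cond) pad
  rates[, conditions, (k + 1L):n_t] <- pop$rates[, conditions, 1:(n_t - k)]
  rates[, conditions, 1:k] <- array(first, dim = c(d[1], length(conditions), k))
  population_peth(rates, pop$grid, pop$neuron_ids, pop$condition_ids,
                  raw = pop$raw)
}

#' Cross-correlation lag between two PETHs
#'
#' Scans integer-bin lags and returns the lag (in ms) at which the Pearson
#' correlation between the two series, computed over their overlapping
#' support, is maximal. A positive lag means `y` is delayed relative to
#' `x`.
#'
#' @param x,y numeric vectors of equal length (rate time courses).
#' @param step_ms grid step, ms.
#' @param max_lag_ms largest lag magnitude scanned; default half the window.
#' @return Lag in ms maximizing the overlap correlation.
#' @export
cross_correlation_lag <- function(x, y, step_ms,
                                  max_lag_ms = (length(x) %/% 2) * step_ms) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  kmax <- min(as.integer(round(max_lag_ms / step_ms)), n - 3L)
  lags <- (-kmax):kmax
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      xa <- x[1:(n - k)]; ya <- y[(1 + k):n]
    } else {
      xa <- x[(1 - k):n]; ya <- y[1:(n + k)]
    }
    if (stats::sd(xa) == 0 || stats::sd(ya) == 0) return(-Inf)
    stats::cor(xa, ya)
  }, numeric(1))
  lags[which.max(r)] * step_ms
}
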