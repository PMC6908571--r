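#' Gaussian PETH kernel
#'
#' Evaluates `amplitude * exp(-(t - tau)^2 / width_param)` on a time grid —
#' the elementary response shape from which all simulated PETHs are built.
#' `width_param` is the divisor of the squared deviation (ms^2), so the
#' default 50 gives a Gaussian with standard deviation `sqrt(50/2) = 5` ms.
#'
#' @param grid a [time_grid()].
#' @param tau peak time, ms. Need not lie on the grid.
#' @param amplitude peak rate (attained exactly when `tau` is a grid point).
#' @param width_param positive width parameter, ms^2.
#' @return Numeric vector of rates over `grid$times`.
#' @examples
#' g <- time_grid()
#' b <- gaussian_bump(g, tau = 0, amplitude = 1)
#' b[g$times == 0]    # 1
#' @export
gaussian_bump <- function(grid, tau, amplitude = 1, width_param = 50) {
  stopifnot_grid(grid)
  if (!is.numeric(width_param) || length(width_param) != 1L || width_param <= 0)
    stop("'width_param' must be a single positive number (ms^2)")
  if (amplitude < 0) stop("'amplitude' must be nonnegative")
  amplitude * exp(-(grid$times - tau)^2 / width_param)
}

#' Simulator configuration
#'
#' Full parameterization of the synthetic PETH population: every neuron in
#' every condition responds with a Gaussian bump whose peak time follows a
#' fixed temporal sequence (neuron `i` peaks `lag_ms` later than neuron
#' `i-1`) and whose amplitude is drawn once per (neuron, condition) from a
#' uniform interval. Conditions are partitioned into contiguous groups that
#' share a base onset time; within a group, neuron 1 peaks at the group
#' onset.
#'
#' Defaults match the dimensions of the motor-cortex dataset the package's
#' analyses are designed around: 218 neurons, 108 conditions, a -50..550 ms
#' window in 10-ms bins, amplitudes uniform on [0.2, 1.2).
#'
#' @param n_neurons,n_conditions population dimensions.
#' @param grid a [time_grid()].
#' @param lag_ms delay of neuron `i` relative to neuron `i-1`, ms. May be a
#'   fraction of the bin width (the kernel is evaluated in continuous time);
#'   0 gives a synchronous population.
#' @param onsets_ms numeric vector of group base onsets, ms; one entry per
#'   condition group.
#' @param condition_groups optional list of integer vectors partitioning
#'   `1:n_conditions` (one per onset). Default: contiguous near-equal blocks,
#'   remainders assigned to the earliest groups, so 108 conditions with two
#'   onsets split 1-54 / 55-108 and with three onsets 1-36 / 37-72 / 73-108.
#' @param amplitude_range `(low, high)` of the uniform amplitude draw.
#' @param kernel_width_param Gaussian width parameter, ms^2.
#' @param seed integer seed for the amplitude draws.
#' @return An object of class `wave_config` (a validated list).
#' @export
wave_config <- function(n_neurons = 218, n_conditions = 108,
                        grid = time_grid(),
                        lag_ms = 1, onsets_ms = 50,
                        condition_groups = NULL,
                        amplitude_range = c(0.2, 1.2),
                        kernel_width_param = 50,
                        seed = 1L) {
  stopifnot_grid(grid)
  if (n_neurons < 1 || n_conditions < 1)
    stop("need at least one neuron and one condition")
  if (length(amplitude_range) != 2L ||
      amplitude_range[1] >= amplitude_range[2])
    stop("'amplitude_range' must be (low, high) with low < high")
  if (amplitude_range[1] < 0) stop("amplitudes must be nonnegative")
  if (kernel_width_param <= 0) stop("'kernel_width_param' must be positive")
  if (is.null(condition_groups))
    condition_groups <- split_indices(n_conditions, length(onsets_ms))
  if (length(condition_groups) != length(onsets_ms))
    stop("one condition group per onset is required")
  all_idx <- sort(unlist(condition_groups))
  if (!identical(as.integer(all_idx), seq_len(n_conditions)))
    stop("'condition_groups' must partition 1:n_conditions without overlap")
  structure(
    list(n_neurons = as.integer(n_neurons),
         n_conditions = as.integer(n_conditions),
         grid = grid, lag_ms = lag_ms, onsets_ms = onsets_ms,
         condition_groups = lapply(condition_groups, as.integer),
         amplitude_range = amplitude_range,
         kernel_width_param = kernel_width_param,
         seed = as.integer(seed)),
    class = "wave_config"
  )
}

# contiguous near-equal partition; remainder to the earliest blocks,
# so 218 neurons in 3 groups -> sizes 73, 73, 72
split_indices <- function(n, k) {
  if (k < 1 || k > n) stop("cannot split ", n, " items into ", k, " groups")
  base <- n %/% k
  sizes <- rep(base, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  mapply(function(a, b) seq.int(a, b), ends - sizes + 1L, ends,
         SIMPLIFY = FALSE)
}

#' Simulate a wave of population activity
#'
#' Generates a `population_peth` in which neuron `i` of a condition in group
#' `g` peaks at `onsets_ms[g] + (i - 1) * lag_ms`, with per-(neuron,
#' condition) amplitudes drawn uniformly from `amplitude_range`. With
#' `lag_ms > 0` the population expresses a temporal sequence ("activity
#' wave") that is identical across conditions up to the group onset; with
#' `lag_ms = 0` all neurons peak simultaneously.
#'
#' The draw is deterministic given `config$seed`, and the seed only affects
#' amplitudes — peak times are fully determined by the configuration. Onsets
#' that place all response mass outside the window produce near-zero rates
#' and a warning, not an error.
#'
#' @param config a [wave_config()].
#' @return A `population_peth` of dim
#'   `(n_neurons, n_conditions, length(grid$times))`.
#' @examples
#' cfg <- wave_config(n_neurons = 5, n_conditions = 4, onsets_ms = c(50, 200))
#' pop <- simulate_wave(cfg)
#' dim(pop)
#' @export
simulate_wave <- function(config) {
  stopifnot(inherits(config, "wave_config"))
  n_n <- config$n_neurons; n_c <- config$n_conditions
  times <- config$grid$times; n_t <- length(times)

  amp <- with_seed(config$seed, {
    matrix(stats::runif(n_n * n_c,
                        config$amplitude_range[1],
                        config$amplitude_range[2]),
           nrow = n_n, ncol = n_c)
  })

  onset_of_cond <- numeric(n_c)
  for (g in seq_along(config$onsets_ms))
    onset_of_cond[config$condition_groups[[g]]] <- config$onsets_ms[g]

  rates <- array(0, dim = c(n_n, n_c, n_t))
  lagged <- (seq_len(n_n) - 1) * config$lag_ms
  for (cc in seq_len(n_c)) {
    tau <- onset_of_cond[cc] + lagged           # one peak time per neuron
    # (n_n x n_t) kernel matrix for this condition, scaled by amplitudes
    dev2 <- outer(tau, times, function(a, b) (b - a)^2)
    rates[, cc, ] <- amp[, cc] * exp(-dev2 / config$kernel_width_param)
  }

  if (max(rates) < 1e-6 * max(amp))
    warning("configured onsets place essentially all response mass outside the time window")

  population_peth(rates, config$grid)
}

#' Simulate a synchronous population (no temporal sequence)
#'
#' Convenience wrapper around [simulate_wave()] with `lag_ms = 0`: within
#' each condition group every neuron peaks at the same time, so the
#' population carries no temporal sequence. Groups may still differ in
#' onset.
#'
#' @param config a [wave_config()]; its `lag_ms` is overridden to 0.
#' @return A `population_peth`.
#' @export
simulate_synchronous <- function(config) {
  stopifnot(inherits(config, "wave_config"))
  config$lag_ms <- 0
  simulate_wave(config)
}

# run code under a temporary RNG state; restores the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
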