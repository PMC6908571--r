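#' Condition-structured population of PETHs
#'
#' The universal data container of the package: one smoothed peri-event time
#' histogram per neuron per experimental condition, all sampled on a common
#' uniform time grid. Stored as a dense 3-dimensional array indexed
#' (neuron, condition, time).
#'
#' Raw firing-rate populations must be nonnegative and finite; populations
#' produced by standardization or cross-condition mean subtraction carry the
#' same class but are on a signed, dimensionless scale (`raw = FALSE`).
#'
#' @param rates numeric array, dim `(n_neurons, n_conditions, n_times)`.
#' @param grid a [time_grid()] whose length matches `dim(rates)[3]`.
#' @param neuron_ids,condition_ids optional label vectors; defaults are
#'   `n1..`, `c1..`.
#' @param raw logical; if `TRUE` (default) rates are validated nonnegative.
#'
#' @return An object of class `population_peth`.
#' @export
population_peth <- function(rates, grid, neuron_ids = NULL,
                            condition_ids = NULL, raw = TRUE) {
  stopifnot_grid(grid)
  if (!is.array(rates) || length(dim(rates)) != 3L)
    stop("'rates' must be a 3-d array (neuron, condition, time)")
  if (dim(rates)[3] != length(grid$times))
    stop("time axis of 'rates' (", dim(rates)[3],
         ") does not match the grid (", length(grid$times), " samples)")
  if (!all(is.finite(rates)))
    stop("'rates' contains non-finite values")
  if (raw && any(rates < 0))
    stop("raw firing rates must be nonnegative")
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(dim(rates)[1]))
  if (is.null(condition_ids)) condition_ids <- paste0("c", seq_len(dim(rates)[2]))
  if (length(neuron_ids) != dim(rates)[1] ||
      length(condition_ids) != dim(rates)[2])
    stop("id lengths do not match 'rates' dimensions")
  structure(
    list(rates = rates, grid = grid,
         neuron_ids = as.character(neuron_ids),
         condition_ids = as.character(condition_ids),
         raw = isTRUE(raw)),
    class = "population_peth"
  )
}

#' @export
print.population_peth <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("population_peth: %d neurons x %d conditions x %d time bins\n",
              d[1], d[2], d[3]))
  cat(sprintf("  window %g to %g ms (step %g ms), %s rates in [%.4g, %.4g]\n",
              x$grid$start, x$grid$stop, x$grid$step,
              if (x$raw) "raw" else "transformed",
              min(x$rates), max(x$rates)))
  invisible(x)
}

#' @export
dim.population_peth <- function(x) dim(x$rates)

#' Long-format view of a PETH population
#'
#' @param x a `population_peth`.
#' @param row.names,optional,... ignored; present for S3 consistency.
#' @return A data frame with columns `neuron`, `condition`, `time_ms`, `rate`.
#' @export
as.data.frame.population_peth <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  d <- dim(x$rates)
  data.frame(
    neuron = rep(x$neuron_ids, times = d[2] * d[3]),
    condition = rep(rep(x$condition_ids, each = d[1]), times = d[3]),
    time_ms = rep(x$grid$times, each = d[1] * d[2]),
    rate = as.vector(x$rates)
  )
}

#' Write / read a PETH population as plain text
#'
#' The on-disk container is a long-format CSV (`neuron`, `condition`,
#' `time_ms`, `rate`) plus a JSON sidecar (`<path>.json`) recording the time
#' grid and axis labels, so a population round-trips exactly.
#'
#' @param pop a `population_peth`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_population_csv` returns `path` invisibly;
#'   `read_population_csv` returns a `population_peth`.
#' @export
write_population_csv <- function(pop, path) {
  stopifnot(inherits(pop, "population_peth"))
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  meta <- list(
    grid = pop$grid[c("start", "stop", "step")],
    neuron_ids = pop$neuron_ids,
    condition_ids = pop$condition_ids,
    raw = pop$raw
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- time_grid(meta$grid$start, meta$grid$stop, meta$grid$step)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ni <- match(df$neuron, meta$neuron_ids)
  ci <- match(df$condition, meta$condition_ids)
  ti <- match(df$time_ms, grid$times)
  rates <- array(NA_real_, dim = c(length(meta$neuron_ids),
                                   length(meta$condition_ids),
                                   length(grid$times)))
  rates[cbind(ni, ci, ti)] <- df$rate
  if (anyNA(rates)) stop("CSV does not cover the full (neuron, condition, time) cube")
  population_peth(rates, grid, meta$neuron_ids, meta$condition_ids,
                  raw = isTRUE(meta$raw))
}

# Frobenius norm of an array
fnorm <- function(x) sqrt(sum(x^2))
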