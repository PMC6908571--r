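#' Uniform peri-event time grid
#'
#' Constructs the uniform time axis on which all PETHs in a population are
#' sampled. The default, -50 to 550 ms in 10-ms bins, is the analysis window
#' used throughout the package and yields 61 samples including both endpoints.
#'
#' @param start window start, ms relative to the alignment event.
#' @param stop window end, ms. Must exceed `start`.
#' @param step bin width, ms. Must be positive.
#'
#' @return An object of class `time_grid`: a list with `start`, `stop`,
#'   `step` and the sampled `times` vector.
#' @examples
#' g <- time_grid()
#' length(g$times)  # 61
#' @export
time_grid <- function(start = -50, stop = 550, step = 10) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("'step' must be a single positive number (ms)")
  if (stop <= start)
    stop("'stop' must exceed 'start'")
  n <- floor((stop - start) / step) + 1L
  structure(
    list(start = start, stop = stop, step = step,
         times = start + step * (seq_len(n) - 1)),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: %g to %g ms, step %g ms (%d samples)\n",
              x$start, x$stop, x$step, length(x$times)))
  invisible(x)
}

is_time_grid <- function(x) inherits(x, "time_grid")

stopifnot_grid <- function(grid) {
  if (!is_time_grid(grid)) stop("'grid' must be a time_grid object")
  grid
}
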