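#' Average PETHs across conditions
#'
#' Arithmetic mean over the condition axis, giving each neuron's average
#' response time course.
#'
#' @param pop a `population_peth`.
#' @return A `(n_neurons x n_times)` matrix with the grid times attached as
#'   attribute `"times"` and neuron ids as row names.
#' @export
average_across_conditions <- function(pop) {
  stopifnot(inherits(pop, "population_peth"))
  d <- dim(pop$rates)
  avg <- apply(pop$rates, c(1, 3), mean)
  dimnames(avg) <- list(pop$neuron_ids, NULL)
  attr(avg, "times") <- pop$grid$times
  avg
}

#' Order neurons by the time of their peak response
#'
#' For each neuron the peak time is the grid time at which its (average)
#' PETH attains its maximum, ties broken toward the earliest time. The
#' returned ordering sorts neurons by peak time ascending, ties broken by
#' original index, and exposes the temporal sequence of activations in a
#' population. Applying it to already-ordered data returns the identity
#' permutation.
#'
#' An all-constant PETH has no peak; its peak time is reported as the first
#' grid time and flagged `degenerate`.
#'
#' @param avg neuron-by-time matrix, e.g. from
#'   [average_across_conditions()].
#' @param times grid times; defaults to `attr(avg, "times")`.
#' @return An object of class `peak_table`: a data frame with columns
#'   `neuron` (original index), `peak_ms`, `rank`, `degenerate`, plus
#'   attribute `"order"` — the permutation of row indices that sorts neurons
#'   by peak time.
#' @export
order_by_peak <- function(avg, times = attr(avg, "times")) {
  if (!is.matrix(avg) || nrow(avg) == 0L) stop("'avg' must be a nonempty matrix")
  if (is.null(times) || length(times) != ncol(avg))
    stop("'times' must match the number of columns of 'avg'")
  peak_idx <- apply(avg, 1, which.max)       # which.max breaks ties earliest
  degen <- apply(avg, 1, function(r) max(r) == min(r))
  peak_ms <- times[peak_idx]
  ord <- order(peak_ms, seq_len(nrow(avg)))  # stable: ties by original index
  tab <- data.frame(
    neuron = seq_len(nrow(avg)),
    peak_ms = peak_ms,
    rank = order(ord),
    degenerate = degen,
    row.names = rownames(avg)
  )
  attr(tab, "order") <- ord
  class(tab) <- c("peak_table", "data.frame")
  tab
}

#' Per-(neuron, condition) peak times
#'
#' Grid-argmax peak time of every individual PETH — the scatter of peak
#' occurrences across neurons and conditions that visualizes whether the
#' activation sequence persists across conditions.
#'
#' @param pop a `population_peth`.
#' @return Data frame with columns `neuron`, `condition`, `peak_ms`.
#' @export
peak_times <- function(pop) {
  stopifnot(inherits(pop, "population_peth"))
  d <- dim(pop$rates)
  idx <- apply(pop$rates, c(1, 2), which.max)
  data.frame(
    neuron = rep(seq_len(d[1]), times = d[2]),
    condition = rep(seq_len(d[2]), each = d[1]),
    peak_ms = pop$grid$times[as.vector(idx)]
  )
}

#' Amplitude-weighted centroid times
#'
#' Rate-weighted mean time of each neuron's average PETH. For a symmetric
#' kernel fully inside the window the centroid equals the true peak time, so
#' it resolves temporal lags smaller than the bin width where the grid
#' argmax cannot.
#'
#' @param avg neuron-by-time matrix.
#' @param times grid times; defaults to `attr(avg, "times")`.
#' @return Numeric vector of centroid times, ms.
#' @export
centroid_times <- function(avg, times = attr(avg, "times")) {
  if (is.null(times) || length(times) != ncol(avg))
    stop("'times' must match the number of columns of 'avg'")
  unname(as.vector(avg %*% times) / rowSums(avg))
}

#' Split an ordered population into contiguous subpopulations
#'
#' Partitions the peak-time ranking into `n_groups` contiguous blocks
#' (early, intermediate, late, ...) of near-equal size, remainders assigned
#' to the earliest blocks: 218 neurons in 3 groups gives sizes 73, 73, 72.
#'
#' @param order a `peak_table` from [order_by_peak()].
#' @param n_groups number of subpopulations (default 3).
#' @return An object of class `subpop_split`: list with `group` (integer
#'   group label per original neuron index), `sizes`, and `members` (list of
#'   original neuron indices per group, in rank order).
#' @export
split_subpopulations <- function(order, n_groups = 3) {
  stopifnot(inherits(order, "peak_table"))
  n <- nrow(order)
  if (n_groups < 1 || n_groups > n)
    stop("'n_groups' must be between 1 and the number of neurons")
  blocks <- split_indices(n, n_groups)   # blocks of ranks
  perm <- attr(order, "order")
  members <- lapply(blocks, function(b) perm[b])
  group <- integer(n)
  for (g in seq_along(members)) group[members[[g]]] <- g
  structure(list(group = group,
                 sizes = lengths(members),
                 members = members),
            class = "subpop_split")
}

#' Per-group, per-condition average PETHs
#'
#' Averages raw (un-normalized) rates over the neurons of each
#' subpopulation, separately for every condition. Plotting the groups
#' against each other in 3-d yields the curved traces that mimic the output
#' of rotation-seeking projections.
#'
#' @param pop a `population_peth`.
#' @param split a `subpop_split` from [split_subpopulations()].
#' @return Array of dim `(n_groups, n_conditions, n_times)`.
#' @export
subpopulation_averages <- function(pop, split) {
  stopifnot(inherits(pop, "population_peth"), inherits(split, "subpop_split"))
  d <- dim(pop$rates)
  out <- array(0, dim = c(length(split$members), d[2], d[3]))
  for (g in seq_along(split$members)) {
    idx <- split$members[[g]]
    out[g, , ] <- apply(pop$rates[idx, , , drop = FALSE], c(2, 3), mean)
  }
  out
}

#' Pairwise correlation of neuronal time courses
#'
#' Pearson correlation between the activity patterns of every pair of
#' neurons. By default patterns are the across-condition average PETHs (one
#' value per pair); alternatively all conditions can be appended into one
#' long time course per neuron.
#'
#' Neurons whose pattern has zero variance have undefined correlations;
#' those entries are returned as `NA` with a warning.
#'
#' @param pop a `population_peth`.
#' @param on `"average"` (default) or `"appended"`.
#' @return Symmetric `n_neurons x n_neurons` correlation matrix with unit
#'   diagonal.
#' @export
pairwise_correlation <- function(pop, on = c("average", "appended")) {
  stopifnot(inherits(pop, "population_peth"))
  on <- match.arg(on)
  d <- dim(pop$rates)
  if (d[3] < 2L) stop("need at least two time samples per neuron")
  mat <- if (on == "average") average_across_conditions(pop)
         else matrix(aperm(pop$rates, c(1, 3, 2)), nrow = d[1])
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0))
    warning("zero-variance neuron(s): correlations returned as NA")
  cc <- suppressWarnings(stats::cor(t(mat)))
  diag(cc) <- 1
  dimnames(cc) <- list(pop$neuron_ids, pop$neuron_ids)
  cc
}

#' Normalize a PETH for display
#'
#' Subtracts the mean and divides by the peak value of the original vector:
#' `(x - mean(x)) / max(x)`. Used only to improve the visual display of
#' phase shifts between neurons — never as an analysis preprocessing step.
#'
#' @param x numeric rate vector with `max(x) > 0`.
#' @return Dimensionless vector; invariant under positive rescaling of `x`.
#' @export
normalize_for_display <- function(x) {
  m <- max(x)
  if (m <= 0) stop("peak of the PETH must be positive for display normalization")
  (x - mean(x)) / m
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table: %d neurons, peak times %g to %g ms%s\n",
              nrow(x), min(x$peak_ms), max(x$peak_ms),
              if (any(x$degenerate)) sprintf(" (%d degenerate)",
                                             sum(x$degenerate)) else ""))
  NextMethod()
}
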