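#' Standardize each neuron's appended time series
#'
#' For every neuron, all condition PETHs are appended into one series; the
#' overall mean of that series is subtracted and the result divided by its
#' overall standard deviation, so each neuron's appended series has mean 0
#' and SD 1. This is the preprocessing used for the plain PCA trajectory
#' analysis.
#'
#' @param pop a `population_peth`.
#' @return A `population_peth` with `raw = FALSE`.
#' @export
standardize <- function(pop) {
  stopifnot(inherits(pop, "population_peth"))
  d <- dim(pop$rates)
  flat <- matrix(pop$rates, nrow = d[1])      # neuron x (condition*time)
  mu <- rowMeans(flat)
  sdv <- apply(flat, 1, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance neuron(s): ",
         paste(pop$neuron_ids[sdv == 0], collapse = ", "))
  rates <- array((flat - mu) / sdv, dim = d)
  population_peth(rates, pop$grid, pop$neuron_ids, pop$condition_ids,
                  raw = FALSE)
}

#' Subtract each neuron's across-condition mean PETH
#'
#' The default preprocessing of the jPCA procedure: for each neuron the
#' across-condition average PETH is computed and subtracted from every one
#' of that neuron's condition PETHs, leaving only condition-specific
#' deviations.
#'
#' The returned conditioning report quantifies how much structure survives:
#' `residual_fraction` is the Frobenius norm after subtraction divided by
#' the norm before, and `rank1_residual_fraction` measures what remains
#' after removing each neuron's best rank-1 (scaled common time course)
#' structure across conditions. When either is below `tol` the population is
#' flagged `degenerate`: conditions are (exactly or up to per-condition
#' scaling) identical, the residual carries no consistent temporal
#' structure, and any subsequent dynamical fit will be dominated by noise.
#'
#' @param pop a `population_peth` with at least 2 conditions.
#' @param tol degeneracy tolerance (default 1e-8).
#' @return List with elements `pop` (the mean-subtracted
#'   `population_peth`, `raw = FALSE`) and `report` (class
#'   `conditioning_report`).
#' @export
subtract_condition_mean <- function(pop, tol = 1e-8) {
  stopifnot(inherits(pop, "population_peth"))
  d <- dim(pop$rates)
  if (d[2] < 2L) stop("need at least two conditions")
  avg <- apply(pop$rates, c(1, 3), mean)                 # neuron x time
  rates <- pop$rates - aperm(array(avg, dim = c(d[1], d[3], d[2])),
                             c(1, 3, 2))
  before <- fnorm(pop$rates)
  resid_frac <- if (before > 0) fnorm(rates) / before else 0

  # energy left after the best per-neuron rank-1 fit of the
  # (condition x time) matrix: zero iff conditions are scalings of one
  # common time course
  e_resid <- 0; e_tot <- 0
  for (i in seq_len(d[1])) {
    m <- pop$rates[i, , ]
    sv <- svd(m, nu = 0, nv = 0)$d
    e_tot <- e_tot + sum(sv^2)
    e_resid <- e_resid + sum(sv[-1]^2)
  }
  rank1_frac <- if (e_tot > 0) sqrt(e_resid / e_tot) else 0

  report <- structure(
    list(residual_fraction = resid_frac,
         rank1_residual_fraction = rank1_frac,
         tol = tol,
         degenerate = (resid_frac < tol) || (rank1_frac < tol)),
    class = "conditioning_report"
  )
  out <- population_peth(rates, pop$grid, pop$neuron_ids,
                         pop$condition_ids, raw = FALSE)
  list(pop = out, report = report)
}

#' @export
print.conditioning_report <- function(x, ...) {
  cat(sprintf(paste0("conditioning_report: residual fraction %.3g, ",
                     "rank-1 residual fraction %.3g -> %s\n"),
              x$residual_fraction, x$rank1_residual_fraction,
              if (x$degenerate) "DEGENERATE (ill-conditioned)"
              else "well-conditioned"))
  invisible(x)
}

#' PCA reduction of a PETH population to state trajectories
#'
#' Appends all conditions along time into a `(n_conditions * n_times) x
#' n_neurons` data matrix, column-centers it, and takes the singular value
#' decomposition. The first `k` right singular vectors are the neuron
#' loadings; scores are split back per condition into `(n_times x k)` state
#' trajectories. Each loading column is sign-fixed so that its
#' largest-magnitude entry is positive, making outputs reproducible across
#' linear-algebra backends.
#'
#' @param pop a `population_peth`.
#' @param k number of components to retain (default 6).
#' @param center column-center the appended matrix (default TRUE).
#' @return An object of class `state_trajectories`: list with `scores`
#'   (list of per-condition time-by-k matrices), `loadings` (neurons x k,
#'   orthonormal columns), `var_explained` (fraction per retained
#'   component), `k`, `times`, `condition_ids`.
#' @export
pca_reduce <- function(pop, k = 6, center = TRUE) {
  stopifnot(inherits(pop, "population_peth"))
  d <- dim(pop$rates)
  n_samples <- d[2] * d[3]
  if (k < 1 || k > min(d[1], n_samples))
    stop("'k' must be between 1 and min(n_neurons, total time samples)")
  # rows: condition-major appended time samples; cols: neurons
  X <- matrix(aperm(pop$rates, c(3, 2, 1)), nrow = n_samples, ncol = d[1])
  if (center) X <- sweep(X, 2, colMeans(X))
  sv <- svd(X)
  V <- sv$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- V[, j]; sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  V <- sweep(V, 2, flip, `*`)
  scores_all <- X %*% V
  tot <- sum(sv$d^2)
  ve <- if (tot > 0) sv$d[seq_len(k)]^2 / tot else rep(0, k)
  idx <- split(seq_len(n_samples),
               rep(seq_len(d[2]), each = d[3]))
  scores <- lapply(idx, function(ii) scores_all[ii, , drop = FALSE])
  names(scores) <- pop$condition_ids
  structure(
    list(scores = scores, loadings = V, var_explained = ve, k = k,
         times = pop$grid$times, condition_ids = pop$condition_ids,
         step_ms = pop$grid$step),
    class = "state_trajectories"
  )
}

#' @export
print.state_trajectories <- function(x, ...) {
  cat(sprintf("state_trajectories: %d conditions x %d time bins, k = %d\n",
              length(x$scores), length(x$times), x$k))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = " "), "\n")
  invisible(x)
}

#' Reconstruct the appended data matrix from state trajectories
#'
#' @param traj a `state_trajectories`.
#' @return The rank-`k` reconstruction (appended samples x neurons) of the
#'   centered data matrix.
#' @export
reconstruct_from_scores <- function(traj) {
  stopifnot(inherits(traj, "state_trajectories"))
  do.call(rbind, traj$scores) %*% t(traj$loadings)
}
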