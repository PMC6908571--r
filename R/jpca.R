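#' Forward finite differences of state trajectories
#'
#' Pairs each state sample with its forward first difference: for every
#' condition, `Xdot[t] = (S[t+1] - S[t]) / dt` with `X[t] = S[t]`, the last
#' sample dropped. Conditions are then stacked into one pooled regression
#' set, since a single dynamics matrix is fitted to all conditions jointly.
#'
#' @param traj a `state_trajectories` from [pca_reduce()], or a list of
#'   time-by-k score matrices.
#' @param dt sample spacing, ms; taken from `traj` when available.
#' @return List with `X` and `Xdot` (pooled sample-by-k matrices), `dt`,
#'   and `condition` (condition index per pooled row).
#' @export
finite_differences <- function(traj, dt = NULL) {
  scores <- if (inherits(traj, "state_trajectories")) traj$scores else traj
  if (is.null(dt)) {
    if (inherits(traj, "state_trajectories")) dt <- traj$step_ms
    else stop("'dt' required when 'traj' is a plain list")
  }
  stopifnot(is.list(scores), length(scores) >= 1L)
  Xs <- list(); Ds <- list(); cond <- integer(0)
  for (ci in seq_along(scores)) {
    S <- scores[[ci]]
    if (nrow(S) < 2L) stop("need at least two time samples per condition")
    Xs[[ci]] <- S[-nrow(S), , drop = FALSE]
    Ds[[ci]] <- diff(S) / dt
    cond <- c(cond, rep(ci, nrow(S) - 1L))
  }
  list(X = do.call(rbind, Xs), Xdot = do.call(rbind, Ds),
       dt = dt, condition = cond)
}

#' Least-squares skew-symmetric dynamics fit
#'
#' Fits the linear dynamical model `Xdot = M X` twice: once over all
#' matrices (`M_best`, ordinary least squares) and once constrained to
#' skew-symmetric matrices `M = -t(M)` (`M_skew`). The skew constraint is
#' imposed by parameterizing M with its k(k-1)/2 independent upper-triangle
#' entries and solving the resulting linear least-squares problem, so
#' `M_skew` is antisymmetric by construction, not by projection. A
#' skew-symmetric matrix has purely imaginary eigenvalues, so the fitted
#' flow rotates states about the origin without radial growth or decay.
#'
#' Goodness of fit is reported as the uncentered
#' `r2 = 1 - ||Xdot - X M'||^2 / ||Xdot||^2`; the constrained fit can never
#' beat the unconstrained one, so `r2_skew <= r2_best`.
#'
#' @param X pooled states, samples x k.
#' @param Xdot pooled derivatives, samples x k (units of X per ms).
#' @param dt sample spacing in ms (carried through for frequency reporting).
#' @return An object of class `skew_fit`: `M_skew`, `M_best` (both k x k,
#'   1/ms), `eigenvalues` (of `M_skew`), `omegas` (rad/ms, descending),
#'   `r2_skew`, `r2_best`, `k`, `dt`.
#' @export
fit_skew <- function(X, Xdot, dt = NA_real_) {
  X <- as.matrix(X); Xdot <- as.matrix(Xdot)
  k <- ncol(X)
  stopifnot(ncol(Xdot) == k, nrow(Xdot) == nrow(X))
  if (k < 2L) stop("skew dynamics need at least 2 dimensions")
  if (nrow(X) < k * (k - 1) / 2)
    stop("need at least k(k-1)/2 pooled samples to identify a skew matrix")

  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)   # (a, b), a < b
  n <- nrow(X)
  # stacked-column design: y = c(Xdot[,1], ..., Xdot[,k]); the column for
  # parameter m_ab holds X[,b] in block a and -X[,a] in block b
  A <- matrix(0, n * k, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    A[((a - 1) * n + 1):(a * n), p] <- X[, b]
    A[((b - 1) * n + 1):(b * n), p] <- -X[, a]
  }
  y <- as.vector(Xdot)
  theta <- lstsq(A, y, context = "skew-symmetric dynamics fit")
  M_skew <- matrix(0, k, k)
  M_skew[pairs] <- theta
  M_skew <- M_skew - t(M_skew)      # exact antisymmetry by construction

  # unconstrained fit: Xdot ~ X %*% t(M_best)
  B <- lstsq(X, Xdot, context = "unconstrained dynamics fit")
  M_best <- t(B)

  ss_tot <- sum(Xdot^2)
  r2 <- function(M) {
    if (ss_tot == 0) return(NA_real_)   # all-zero derivatives: fit undefined
    1 - sum((Xdot - X %*% t(M))^2) / ss_tot
  }
  ev <- eigen(M_skew, only.values = TRUE)$values
  structure(
    list(M_skew = M_skew, M_best = M_best, eigenvalues = ev,
         omegas = sort(Im(ev[Im(ev) > 1e-12]), decreasing = TRUE),
         r2_skew = r2(M_skew), r2_best = r2(M_best), k = k, dt = dt),
    class = "skew_fit"
  )
}

# least squares with pseudoinverse fallback on rank deficiency
lstsq <- function(A, y, context = "least squares") {
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    warning("rank-deficient design in ", context,
            ": solving via pseudoinverse (data may be ill-conditioned)")
    sv <- svd(A)
    pos <- sv$d > max(dim(A)) * .Machine$double.eps * sv$d[1]
    di <- ifelse(pos, 1 / sv$d, 0)
    return(sv$v %*% (di * (t(sv$u) %*% as.matrix(y))))
  }
  qr.coef(qrA, as.matrix(y))
}

#' @export
print.skew_fit <- function(x, ...) {
  cat(sprintf("skew_fit: k = %d, r2_skew = %.3f, r2_best = %.3f\n",
              x$k, x$r2_skew, x$r2_best))
  om <- sort(unique(round(x$omegas, 10)), decreasing = TRUE)
  if (length(om))
    cat("  rotation frequencies (rad/ms):",
        paste(sprintf("%.4g", om), collapse = " "), "\n")
  invisible(x)
}

#' Extract rotation planes from a skew-symmetric fit
#'
#' The eigenvalues of a skew-symmetric matrix come in conjugate imaginary
#' pairs `+-i w`. Each pair spans a 2-dimensional invariant plane in which
#' the flow is a pure rotation at angular frequency `w` (rad/ms). Planes
#' are returned sorted by `w` descending ("most prominent" rotation first),
#' each with an orthonormal real 2-column basis built from the real and
#' imaginary parts of one eigenvector of the pair. For odd `k` the single
#' zero eigenvalue spans no plane and is dropped.
#'
#' @param fit a `skew_fit`.
#' @param tol eigenfrequencies below `tol` are treated as zero.
#' @return List of planes; each a list with `omega` (rad/ms) and `basis`
#'   (k x 2 orthonormal matrix).
#' @export
rotation_planes <- function(fit, tol = 1e-12) {
  stopifnot(inherits(fit, "skew_fit"))
  es <- eigen(fit$M_skew)
  keep <- which(Im(es$values) > tol)   # one representative per +-iw pair
  keep <- keep[order(Im(es$values)[keep], decreasing = TRUE)]
  lapply(keep, function(j) {
    v <- es$vectors[, j]
    Braw <- cbind(Re(v), Im(v))
    B <- qr.Q(qr(Braw))
    list(omega = Im(es$values)[j], basis = B)
  })
}

#' Project trajectories onto a rotation plane and summarize directions
#'
#' Projects each condition's state trajectory onto a 2-dimensional plane
#' and measures its signed rotation direction as the sign of the summed
#' cross product of consecutive projected states,
#' `sum_t (x_t y_{t+1} - y_t x_{t+1})` (twice the signed swept area about
#' the origin). Direction consistency is the fraction of conditions sharing
#' the majority sign — the package's operationalization of "rotating in the
#' same direction in all conditions". The plane basis is oriented so the
#' majority rotates counter-clockwise, making plots deterministic.
#'
#' @param traj a `state_trajectories` or list of time-by-k score matrices.
#' @param plane a plane from [rotation_planes()] (list with `omega`,
#'   `basis`), or a bare k x 2 basis matrix.
#' @return An object of class `rotation_summary`: `projections` (list of
#'   time-by-2 matrices), `direction` (+1 counter-clockwise / -1 clockwise
#'   per condition), `signed_area` per condition, `consistency`, `n_ccw`,
#'   `n_cw`, `omega`, `basis` (as oriented).
#' @export
project_and_summarize <- function(traj, plane) {
  scores <- if (inherits(traj, "state_trajectories")) traj$scores else traj
  if (is.matrix(plane)) plane <- list(omega = NA_real_, basis = plane)
  B <- plane$basis
  stopifnot(ncol(B) == 2L, nrow(B) == ncol(scores[[1]]))
  areas <- function(P) sum(P[-nrow(P), 1] * P[-1, 2] - P[-nrow(P), 2] * P[-1, 1])
  proj <- lapply(scores, function(S) S %*% B)
  a <- vapply(proj, areas, numeric(1))
  if (sum(sign(a)) < 0) {                  # orient majority counter-clockwise
    B[, 2] <- -B[, 2]
    proj <- lapply(scores, function(S) S %*% B)
    a <- -a
  }
  s <- sign(a)
  n_ccw <- sum(s > 0); n_cw <- sum(s < 0)
  structure(
    list(projections = proj, direction = s, signed_area = a,
         consistency = max(n_ccw, n_cw) / length(a),
         n_ccw = n_ccw, n_cw = n_cw,
         omega = plane$omega, basis = B),
    class = "rotation_summary"
  )
}

#' @export
print.rotation_summary <- function(x, ...) {
  cat(sprintf(paste0("rotation_summary: %d conditions, %d ccw / %d cw, ",
                     "consistency %.3f"),
              length(x$direction), x$n_ccw, x$n_cw, x$consistency))
  if (is.finite(x$omega)) cat(sprintf(", omega %.4g rad/ms", x$omega))
  cat("\n")
  invisible(x)
}

#' Fit rotational dynamics to a PETH population (jPCA)
#'
#' The full jPCA pipeline: optional subtraction of each neuron's
#' across-condition mean PETH (the procedure's contested default
#' preprocessing), PCA reduction to `num_pcs` components, forward finite
#' differencing, least-squares fit of a skew-symmetric dynamics matrix
#' `Xdot = M_skew X`, extraction of its rotation planes, and projection of
#' all condition trajectories onto the strongest plane with a
#' rotation-direction summary.
#'
#' When mean subtraction leaves (near-)zero condition-specific structure —
#' conditions identical, or identical up to per-condition amplitude scaling
#' — the data are ill-conditioned for the fit: the regression runs on what
#' is essentially noise and the resulting "rotations" are untrustworthy.
#' This state is detected by the conditioning report and propagated as a
#' prominent warning and a `degenerate` flag on the returned object; the
#' fit itself still runs.
#'
#' @param pop a `population_peth`.
#' @param subtract_mean subtract each neuron's across-condition average
#'   PETH before PCA (default TRUE, matching the original procedure).
#' @param num_pcs retained PCA dimensionality (default 6).
#' @param t_start,t_stop analysis window, ms; defaults to the population's
#'   full grid. Must lie within the data grid.
#' @return An object of class `jpca`: components `skew` (the
#'   [fit_skew()] result), `planes`, `top_summary` (a `rotation_summary`
#'   for the strongest plane), `plane_summaries` (one per plane),
#'   `trajectories` (the `state_trajectories`), `conditioning`
#'   (a `conditioning_report`, or NULL when `subtract_mean = FALSE`),
#'   `degenerate`, `call`.
#' @examples
#' cfg <- wave_config(n_neurons = 40, n_conditions = 20,
#'                    onsets_ms = c(50, 200), lag_ms = 5, seed = 2)
#' fit <- jpca(simulate_wave(cfg))
#' fit
#' @export
jpca <- function(pop, subtract_mean = TRUE, num_pcs = 6,
                 t_start = NULL, t_stop = NULL) {
  stopifnot(inherits(pop, "population_peth"))
  g <- pop$grid
  if (is.null(t_start)) t_start <- g$start
  if (is.null(t_stop)) t_stop <- g$stop
  if (t_start < g$start - 1e-9 || t_stop > g$stop + 1e-9 || t_stop <= t_start)
    stop("analysis window [", t_start, ", ", t_stop,
         "] must lie within the data grid [", g$start, ", ", g$stop, "]")
  keep <- which(g$times >= t_start - 1e-9 & g$times <= t_stop + 1e-9)
  if (length(keep) < length(g$times)) {
    sub <- time_grid(g$times[keep[1]], g$times[keep[length(keep)]], g$step)
    pop <- population_peth(pop$rates[, , keep, drop = FALSE], sub,
                           pop$neuron_ids, pop$condition_ids, raw = pop$raw)
  }

  conditioning <- NULL
  if (subtract_mean) {
    ms <- subtract_condition_mean(pop)
    pop_fit <- ms$pop
    conditioning <- ms$report
    if (conditioning$degenerate)
      warning("data are ill-conditioned after cross-condition mean ",
              "subtraction (residual fraction ",
              signif(conditioning$residual_fraction, 3),
              ", rank-1 residual fraction ",
              signif(conditioning$rank1_residual_fraction, 3),
              "): the skew fit runs on noise and its rotations are not ",
              "trustworthy")
  } else {
    pop_fit <- pop
  }

  traj <- pca_reduce(pop_fit, k = num_pcs)
  fd <- finite_differences(traj)
  skew <- fit_skew(fd$X, fd$Xdot, dt = fd$dt)
  planes <- rotation_planes(skew)
  plane_summaries <- lapply(planes, function(p) project_and_summarize(traj, p))
  top <- if (length(plane_summaries)) plane_summaries[[1]] else NULL
  structure(
    list(skew = skew, planes = planes, top_summary = top,
         plane_summaries = plane_summaries, trajectories = traj,
         conditioning = conditioning,
         degenerate = !is.null(conditioning) && conditioning$degenerate,
         subtract_mean = subtract_mean, num_pcs = num_pcs,
         window = c(t_start, t_stop),
         pooled = fd, call = match.call()),
    class = "jpca"
  )
}

#' @export
print.jpca <- function(x, ...) {
  cat("jPCA skew-symmetric dynamics fit\n")
  cat(sprintf("  %d conditions, k = %d PCs, mean subtraction %s\n",
              length(x$trajectories$scores), x$num_pcs,
              if (x$subtract_mean) "on" else "off"))
  cat(sprintf("  r2_skew = %.3f, r2_best = %.3f\n",
              x$skew$r2_skew, x$skew$r2_best))
  if (!is.null(x$top_summary))
    cat(sprintf("  top plane: omega %.4g rad/ms, direction consistency %.3f\n",
                x$top_summary$omega, x$top_summary$consistency))
  if (x$degenerate)
    cat("  WARNING: ill-conditioned (degenerate) input; rotations untrusted\n")
  invisible(x)
}

#' @export
summary.jpca <- function(object, ...) {
  out <- list(
    num_pcs = object$num_pcs,
    n_conditions = length(object$trajectories$scores),
    subtract_mean = object$subtract_mean,
    r2_skew = object$skew$r2_skew,
    r2_best = object$skew$r2_best,
    omegas = vapply(object$planes, `[[`, numeric(1), "omega"),
    consistency = vapply(object$plane_summaries, `[[`, numeric(1),
                         "consistency"),
    var_explained = object$trajectories$var_explained,
    degenerate = object$degenerate,
    conditioning = object$conditioning
  )
  class(out) <- "summary.jpca"
  out
}

#' @export
print.summary.jpca <- function(x, ...) {
  cat("jPCA fit summary\n")
  cat(sprintf("  PCs: %d (%.1f%% variance), %d conditions, mean subtraction %s\n",
              x$num_pcs, 100 * sum(x$var_explained), x$n_conditions,
              if (x$subtract_mean) "on" else "off"))
  cat(sprintf("  r2_skew = %.3f, r2_best = %.3f (ratio %.3f)\n",
              x$r2_skew, x$r2_best,
              if (x$r2_best != 0) x$r2_skew / x$r2_best else NA))
  if (length(x$omegas)) {
    cat("  planes (omega rad/ms : direction consistency):\n")
    for (i in seq_along(x$omegas))
      cat(sprintf("    %.4g : %.3f\n", x$omegas[i], x$consistency[i]))
  }
  if (x$degenerate) {
    cat("  DEGENERATE: ")
    print(x$conditioning)
  }
  invisible(x)
}

#' @export
coef.jpca <- function(object, which = c("skew", "best"), ...) {
  which <- match.arg(which)
  if (which == "skew") object$skew$M_skew else object$skew$M_best
}

#' @export
fitted.jpca <- function(object, ...) {
  object$pooled$X %*% t(object$skew$M_skew)
}

#' @export
residuals.jpca <- function(object, ...) {
  object$pooled$Xdot - fitted(object)
}

#' Plot top-plane trajectories of a jPCA fit
#'
#' Draws every condition's trajectory projected onto the strongest rotation
#' plane, with a dot at each starting state. Consistent same-direction
#' circles are the signature the procedure is designed to surface.
#'
#' @param x a `jpca` object.
#' @param conditions which conditions to draw (default all).
#' @param col line colors, recycled.
#' @param ... passed to [graphics::plot()].
#' @export
plot.jpca <- function(x, conditions = NULL,
                      col = grDevices::hcl.colors(12, "Zissou 1"), ...) {
  if (is.null(x$top_summary)) stop("fit has no rotation plane to plot")
  proj <- x$top_summary$projections
  if (is.null(conditions)) conditions <- seq_along(proj)
  rng <- range(unlist(proj[conditions]))
  graphics::plot(NA, xlim = rng, ylim = rng, asp = 1,
                 xlab = "plane axis 1", ylab = "plane axis 2",
                 main = sprintf("top rotation plane (consistency %.2f)",
                                x$top_summary$consistency), ...)
  col <- rep_len(col, length(conditions))
  for (i in seq_along(conditions)) {
    P <- proj[[conditions[i]]]
    graphics::lines(P[, 1], P[, 2], col = col[i])
    graphics::points(P[1, 1], P[1, 2], pch = 16, cex = 0.6, col = col[i])
  }
  invisible(x)
}
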