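#' Lissajous target curves
#'
#' Parametric 2-d target curves evaluated on a time grid, with time measured
#' from the window start: the unit circle
#' `x = cos(2*pi*t/T), y = sin(2*pi*t/T)` and the figure-eight
#' (`infinity`) curve `x = cos(2*pi*t/T), y = sin(4*pi*t/T)`. These are the
#' arbitrary shapes that multiple linear regression can read out of a
#' neuronal population.
#'
#' @param grid a [time_grid()].
#' @param shape `"circle"` or `"infinity"`.
#' @param period curve period `T`, ms; defaults to the window duration so
#'   the circle closes exactly once per window.
#' @return An object of class `lissajous_target`: list with `x`, `y`,
#'   `times`, `shape`, `period`.
#' @examples
#' tg <- lissajous_target(time_grid(), "circle")
#' all.equal(tg$x^2 + tg$y^2, rep(1, length(tg$x)))
#' @export
lissajous_target <- function(grid, shape = c("circle", "infinity"),
                             period = NULL) {
  stopifnot_grid(grid)
  shape <- match.arg(shape)
  if (is.null(period)) period <- grid$stop - grid$start
  if (period <= 0) stop("'period' must be positive")
  t <- grid$times - grid$start
  structure(
    list(x = cos(2 * pi * t / period),
         y = if (shape == "circle") sin(2 * pi * t / period)
             else sin(4 * pi * t / period),
         times = grid$times, shape = shape, period = period),
    class = "lissajous_target"
  )
}

#' Fit a population to a Lissajous curve by multiple linear regression
#'
#' Two independent ordinary least-squares regressions (one per output
#' coordinate) of the target curve, tiled across the training conditions,
#' on the neuron-rate design matrix: rows are the appended time samples of
#' the training conditions, columns are neurons, plus an intercept column
#' by default. With enough neurons relative to samples the design can
#' reproduce practically any target — the point of the exercise.
#'
#' @param pop a `population_peth`.
#' @param target a [lissajous_target()] on the same grid.
#' @param train_conditions condition indices used for fitting; default all.
#' @param intercept include an intercept column (default TRUE).
#' @return An object of class `lissajous_fit`: `coefficients`
#'   (`(n_neurons + intercept) x 2`, columns `x`, `y`), `r2_train` (length
#'   2), `fitted` (list of time-by-2 curves per training condition),
#'   `train_conditions`, `target`, `intercept`.
#' @export
lissajous_fit <- function(pop, target, train_conditions = NULL,
                          intercept = TRUE) {
  stopifnot(inherits(pop, "population_peth"),
            inherits(target, "lissajous_target"))
  d <- dim(pop$rates)
  if (!isTRUE(all.equal(target$times, pop$grid$times)))
    stop("target and population are on different time grids")
  if (is.null(train_conditions)) train_conditions <- seq_len(d[2])
  train_conditions <- sort(unique(as.integer(train_conditions)))
  if (any(train_conditions < 1L | train_conditions > d[2]))
    stop("'train_conditions' out of range")
  D <- design_matrix(pop, train_conditions, intercept)
  if (nrow(D) <= d[1] + as.integer(intercept))
    warning("pooled training samples do not exceed the number of ",
            "predictors; fit is an interpolation")
  Y <- cbind(x = rep(target$x, times = length(train_conditions)),
             y = rep(target$y, times = length(train_conditions)))
  beta <- lstsq(D, Y, context = "Lissajous regression")
  colnames(beta) <- c("x", "y")
  fit_vals <- D %*% beta
  r2 <- r2_columns(Y, fit_vals)
  n_t <- d[3]
  fitted_curves <- lapply(seq_along(train_conditions), function(i) {
    fit_vals[((i - 1) * n_t + 1):(i * n_t), , drop = FALSE]
  })
  names(fitted_curves) <- pop$condition_ids[train_conditions]
  structure(
    list(coefficients = beta, r2_train = r2, fitted = fitted_curves,
         train_conditions = train_conditions, target = target,
         intercept = intercept, n_neurons = d[1]),
    class = "lissajous_fit"
  )
}

# appended-time design matrix for a set of conditions (condition-major rows)
design_matrix <- function(pop, conditions, intercept) {
  d <- dim(pop$rates)
  blocks <- lapply(conditions, function(cc) t(pop$rates[, cc, ]))  # time x neuron
  D <- do.call(rbind, blocks)
  if (intercept) D <- cbind(`(Intercept)` = 1, D)
  D
}

# centered R^2 per output column
r2_columns <- function(Y, Yhat) {
  vapply(seq_len(ncol(Y)), function(j) {
    sst <- sum((Y[, j] - mean(Y[, j]))^2)
    1 - sum((Y[, j] - Yhat[, j])^2) / sst
  }, numeric(1))
}

#' Predict Lissajous curves for held-out conditions
#'
#' Applies the fitted regression weights to a set of test conditions and
#' scores the predictions against the same target curve. The test set must
#' be disjoint from the training set unless `allow_overlap = TRUE` (used
#' e.g. to verify that scoring the training set reproduces `r2_train`).
#'
#' @param object a `lissajous_fit`.
#' @param pop the `population_peth` to predict from.
#' @param test_conditions condition indices to predict.
#' @param allow_overlap permit train/test overlap (default FALSE).
#' @param ... unused.
#' @return List with `curves` (per-condition time-by-2 predictions) and
#'   `r2_test` (length 2, columns x and y).
#' @export
predict.lissajous_fit <- function(object, pop, test_conditions,
                                  allow_overlap = FALSE, ...) {
  stopifnot(inherits(pop, "population_peth"))
  d <- dim(pop$rates)
  test_conditions <- sort(unique(as.integer(test_conditions)))
  if (any(test_conditions < 1L | test_conditions > d[2]))
    stop("'test_conditions' out of range")
  if (!allow_overlap &&
      length(intersect(test_conditions, object$train_conditions)))
    stop("test conditions overlap the training set")
  if (d[1] != object$n_neurons)
    stop("population has a different number of neurons than the fit")
  D <- design_matrix(pop, test_conditions, object$intercept)
  pred <- D %*% object$coefficients
  Y <- cbind(x = rep(object$target$x, times = length(test_conditions)),
             y = rep(object$target$y, times = length(test_conditions)))
  n_t <- d[3]
  curves <- lapply(seq_along(test_conditions), function(i) {
    pred[((i - 1) * n_t + 1):(i * n_t), , drop = FALSE]
  })
  names(curves) <- pop$condition_ids[test_conditions]
  list(curves = curves, r2_test = r2_columns(Y, pred))
}

#' @export
print.lissajous_fit <- function(x, ...) {
  cat(sprintf(paste0("lissajous_fit: %s target, %d neurons%s, ",
                     "%d training conditions\n"),
              x$target$shape, x$n_neurons,
              if (x$intercept) " + intercept" else "",
              length(x$train_conditions)))
  cat(sprintf("  r2_train: x %.3f, y %.3f\n", x$r2_train[1], x$r2_train[2]))
  invisible(x)
}

#' @export
coef.lissajous_fit <- function(object, ...) object$coefficients

#' Plot fitted or predicted Lissajous curves
#'
#' @param x a `lissajous_fit`.
#' @param curves optional list of time-by-2 curves (e.g. from
#'   [predict.lissajous_fit()]); default the training fits.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lissajous_fit <- function(x, curves = NULL, ...) {
  if (is.null(curves)) curves <- x$fitted
  rng <- range(unlist(curves), x$target$x, x$target$y)
  graphics::plot(NA, xlim = rng, ylim = rng, asp = 1, xlab = "x", ylab = "y",
                 main = sprintf("%s readout", x$target$shape), ...)
  for (P in curves) graphics::lines(P[, 1], P[, 2], col = "grey50")
  graphics::lines(x$target$x, x$target$y, col = "red", lwd = 2)
  invisible(x)
}

#' Even/odd train-test split of conditions
#'
#' Default "half of the conditions" split used for generalization tests:
#' odd-indexed conditions train, even-indexed test. A seeded random split
#' is available instead.
#'
#' @param n_conditions total number of conditions.
#' @param type `"even_odd"` (default) or `"random"`.
#' @param seed seed for the random split.
#' @return List with integer vectors `train` and `test`.
#' @export
condition_split <- function(n_conditions, type = c("even_odd", "random"),
                            seed = 1L) {
  type <- match.arg(type)
  idx <- seq_len(n_conditions)
  if (type == "even_odd") {
    list(train = idx[idx %% 2 == 1L], test = idx[idx %% 2 == 0L])
  } else {
    tr <- with_seed(seed, sort(sample(idx, ceiling(n_conditions / 2))))
    list(train = tr, test = setdiff(idx, tr))
  }
}
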