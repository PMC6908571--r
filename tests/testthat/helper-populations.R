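# small fixtures built in code

# population from an explicit (neuron x condition x time) array
make_pop <- function(rates, grid = NULL, raw = TRUE) {
  if (is.null(grid)) {
    n_t <- dim(rates)[3]
    grid <- time_grid(0, 10 * (n_t - 1), 10)
  }
  population_peth(rates, grid, raw = raw)
}

# two neurons, 1 + sin and 1 + cos over the window, identical in every
# condition: the textbook phase-shifted pair that traces a circle
two_neuron_sincos <- function(n_conditions = 8, grid = time_grid()) {
  t <- grid$times - grid$start
  period <- grid$stop - grid$start
  r <- rbind(1 + sin(2 * pi * t / period),
             1 + cos(2 * pi * t / period))
  rates <- array(0, dim = c(2, n_conditions, length(t)))
  for (cc in seq_len(n_conditions)) rates[, cc, ] <- r
  population_peth(rates, grid)
}

# noiseless planar rotation sampled at dt over one period
circle_scores <- function(omega, dt, period = 2 * pi / omega) {
  t <- seq(0, period, by = dt)
  cbind(cos(omega * t), sin(omega * t))
}

# independent oracle: solve A M + M A = Xdot'X - X'Xdot for skew M
# (stationarity condition of the constrained least-squares problem)
lyapunov_skew <- function(X, Xdot) {
  A <- crossprod(X)
  C <- crossprod(Xdot, X) - crossprod(X, Xdot)
  e <- eigen(A, symmetric = TRUE)
  Ct <- t(e$vectors) %*% C %*% e$vectors
  Mt <- Ct / outer(e$values, e$values, `+`)
  e$vectors %*% Mt %*% t(e$vectors)
}

# independent oracle: direct numerical minimization over the
# upper-triangle parameterization (k <= 3 keeps optim reliable)
optim_skew <- function(X, Xdot) {
  k <- ncol(X)
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  build <- function(theta) {
    M <- matrix(0, k, k); M[pairs] <- theta; M - t(M)
  }
  obj <- function(theta) sum((Xdot - X %*% t(build(theta)))^2)
  fit <- stats::optim(rep(0, nrow(pairs)), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  build(fit$par)
}
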