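test_that("forward differences pair left samples with scaled increments", {
  t <- seq(0, 100, 10)
  ramp <- cbind(2 * t, -0.5 * t)
  fd <- finite_differences(list(ramp), dt = 10)
  expect_equal(fd$Xdot, matrix(rep(c(2, -0.5), each = 10), ncol = 2),
               tolerance = 1e-12)
  expect_equal(fd$X, ramp[-nrow(ramp), ], tolerance = 1e-14)

  const <- matrix(5, nrow = 8, ncol = 3)
  expect_true(all(finite_differences(list(const), dt = 1)$Xdot == 0))

  # first-order accuracy: halving dt shrinks the derivative error
  om <- 0.02
  err <- function(dt) {
    S <- circle_scores(om, dt)
    fd <- finite_differences(list(S), dt = dt)
    t_left <- (seq_len(nrow(fd$X)) - 1) * dt
    truth <- cbind(-om * sin(om * t_left), om * cos(om * t_left))
    max(abs(fd$Xdot - truth))
  }
  expect_lt(err(0.1), err(1))
  expect_lt(err(1), 0.05 * om)   # O(dt): error ~ om^2 dt / 2
})

test_that("skew fit recovers the planar rotation generator analytically", {
  om <- 0.03
  t <- seq(0, 2 * pi / om, by = 1)
  X <- cbind(cos(om * t), sin(om * t))
  Xdot <- cbind(-om * sin(om * t), om * cos(om * t))
  fit <- fit_skew(X, Xdot, dt = 1)
  expect_equal(fit$M_skew, matrix(c(0, om, -om, 0), 2), tolerance = 1e-8)
  expect_equal(fit$r2_skew, 1, tolerance = 1e-10)
  # exactly skew-generated derivatives: constrained fit matches the free one
  expect_lte(fit$r2_best - fit$r2_skew, 1e-10)
})

test_that("solver agrees with the Lyapunov-equation and direct oracles", {
  set.seed(42)
  for (k in c(2, 3, 6)) {
    X <- matrix(rnorm(60 * k), ncol = k)
    Xdot <- matrix(rnorm(60 * k), ncol = k)
    fit <- fit_skew(X, Xdot)
    # antisymmetry holds exactly, by construction
    expect_identical(fit$M_skew + t(fit$M_skew), matrix(0, k, k))
    # normal-equations (Lyapunov) oracle
    M_lyap <- lyapunov_skew(X, Xdot)
    expect_equal(fit$M_skew, M_lyap, tolerance = 1e-8)
    # direct numerical minimization, kept to small k
    if (k <= 3) {
      M_opt <- optim_skew(X, Xdot)
      expect_lt(max(abs(fit$M_skew - M_opt)) / max(abs(fit$M_skew)), 1e-6)
    }
    expect_lte(fit$r2_skew, fit$r2_best + 1e-12)
  }
})

test_that("rotation frequency is recovered within 1% from 1-ms sampling", {
  om <- 0.02
  est <- function(dt) {
    fd <- finite_differences(list(circle_scores(om, dt)), dt = dt)
    fit_skew(fd$X, fd$Xdot, dt = dt)$omegas[1]
  }
  expect_lt(abs(est(1) - om) / om, 0.01)
  # first-order scheme: the bias shrinks with dt
  expect_lt(abs(est(0.25) - om), abs(est(1) - om))
})

test_that("the fit is equivariant under orthogonal changes of basis", {
  set.seed(7)
  k <- 4
  X <- matrix(rnorm(80 * k), ncol = k)
  Xdot <- matrix(rnorm(80 * k), ncol = k)
  Q <- qr.Q(qr(matrix(rnorm(k * k), k)))
  f0 <- fit_skew(X, Xdot)
  f1 <- fit_skew(X %*% t(Q), Xdot %*% t(Q))
  expect_equal(f1$M_skew, Q %*% f0$M_skew %*% t(Q), tolerance = 1e-8)
  expect_equal(sort(f1$omegas), sort(f0$omegas), tolerance = 1e-8)
  expect_equal(f1$r2_skew, f0$r2_skew, tolerance = 1e-8)
  expect_equal(f1$r2_best, f0$r2_best, tolerance = 1e-8)
})

test_that("rotation planes are ordered by frequency with orthonormal bases", {
  M <- matrix(c(0, 1, -1, 0), 2)
  fit <- structure(list(M_skew = M, k = 2), class = "skew_fit")
  pl <- rotation_planes(fit)
  expect_length(pl, 1L)
  expect_equal(pl[[1]]$omega, 1, tolerance = 1e-12)

  # block-diagonal with omega 0.5 and 2.0: planes ordered (2.0, 0.5)
  B <- matrix(0, 4, 4)
  B[1:2, 1:2] <- matrix(c(0, 0.5, -0.5, 0), 2)
  B[3:4, 3:4] <- matrix(c(0, 2, -2, 0), 2)
  fitB <- structure(list(M_skew = B, k = 4), class = "skew_fit")
  plB <- rotation_planes(fitB)
  expect_equal(vapply(plB, `[[`, numeric(1), "omega"), c(2, 0.5),
               tolerance = 1e-10)
  for (p in plB)
    expect_equal(crossprod(p$basis), diag(2), tolerance = 1e-10)

  # odd k: the unpaired zero eigenvalue spans no plane
  C <- matrix(0, 3, 3); C[1, 2] <- -1; C[2, 1] <- 1
  plC <- rotation_planes(structure(list(M_skew = C, k = 3),
                                   class = "skew_fit"))
  expect_length(plC, 1L)
})

test_that("direction summaries count rotation signs per condition", {
  om <- 0.02
  S <- circle_scores(om, 10)
  same <- replicate(6, S, simplify = FALSE)
  rs <- project_and_summarize(same, diag(2))
  expect_equal(rs$consistency, 1)
  expect_identical(rs$n_ccw, 6L + 0L)

  # half traversed in reversed time: consistency drops to 1/2
  mixed <- c(replicate(3, S, simplify = FALSE),
             replicate(3, S[nrow(S):1, ], simplify = FALSE))
  rs2 <- project_and_summarize(mixed, diag(2))
  expect_equal(rs2$consistency, 0.5)
})

test_that("jpca pipeline reproduces the two-neuron phase-shift vignette", {
  pop <- two_neuron_sincos(n_conditions = 6)

  # without mean subtraction the circle is found in every condition
  f_off <- jpca(pop, subtract_mean = FALSE, num_pcs = 2)
  expect_false(f_off$degenerate)
  expect_equal(f_off$top_summary$consistency, 1)
  expect_gt(f_off$skew$r2_skew, 0.9)

  # with mean subtraction, identical conditions leave nothing to fit
  # (the degenerate fit also falls back to the pseudoinverse, so several
  # warnings are raised; the conditioning one must be among them)
  w <- capture_warnings(f_on <- jpca(pop, subtract_mean = TRUE, num_pcs = 2))
  expect_true(any(grepl("ill-conditioned", w)))
  expect_true(f_on$degenerate)
  expect_lt(f_on$conditioning$residual_fraction, 1e-10)
})

test_that("jpca windows are validated and applied", {
  pop <- simulate_wave(wave_config(n_neurons = 10, n_conditions = 6,
                                   onsets_ms = c(100, 300), lag_ms = 10,
                                   seed = 4))
  expect_error(jpca(pop, t_start = -500), "within the data grid")
  expect_error(jpca(pop, t_stop = 900), "within the data grid")
  f <- jpca(pop, num_pcs = 4, t_start = 0, t_stop = 400)
  expect_identical(length(f$trajectories$times), 41L)
  expect_identical(range(f$trajectories$times), c(0, 400))
})
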