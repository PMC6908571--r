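test_that("gaussian bump matches its closed form on the grid", {
  g <- time_grid()

  # peak value equals the amplitude when tau is a grid point
  b <- gaussian_bump(g, tau = 250, amplitude = 0.7)
  expect_identical(b[g$times == 250], 0.7)
  expect_equal(max(b), 0.7)

  # closed-form evaluation 5 ms off-peak: exp(-25/50)
  g1 <- time_grid(-50, 550, 5)
  b1 <- gaussian_bump(g1, tau = 0, amplitude = 1)
  expect_equal(b1[g1$times == 5], exp(-0.5), tolerance = 1e-12)
  expect_equal(b1[g1$times == -5], exp(-0.5), tolerance = 1e-12)

  # numerically negligible at the window edge far from the peak
  b2 <- gaussian_bump(g, tau = 250, amplitude = 1)
  expect_lt(b2[g$times == -50], 1e-100)

  expect_error(gaussian_bump(g, 0, 1, width_param = 0), "width_param")
  expect_error(gaussian_bump(g, 0, 1, width_param = -5), "width_param")
})

test_that("wave simulation has the configured shape and peak structure", {
  cfg <- wave_config(onsets_ms = c(50, 200), lag_ms = 1, seed = 1)
  pop <- simulate_wave(cfg)
  expect_identical(dim(pop), c(218L, 108L, 61L))
  expect_true(all(pop$rates >= 0))

  # neuron 1 peaks at the group onset: 50 ms in conditions 1-54,
  # 200 ms in conditions 55-108
  g <- pop$grid
  expect_identical(g$times[which.max(pop$rates[1, 1, ])], 50)
  expect_identical(g$times[which.max(pop$rates[1, 54, ])], 50)
  expect_identical(g$times[which.max(pop$rates[1, 55, ])], 200)
  expect_identical(g$times[which.max(pop$rates[1, 60, ])], 200)
})

test_that("amplitude-weighted centroids advance by the configured lag", {
  # bumps fully inside the window; centroid of a symmetric kernel is tau.
  # a 1-ms grid keeps the discrete centroid free of sampling alias, which
  # a 10-ms grid cannot do for a 5-ms-SD kernel with sub-bin lags
  cfg <- wave_config(n_neurons = 20, n_conditions = 6, onsets_ms = 250,
                     lag_ms = 1, grid = time_grid(-50, 550, 1), seed = 3)
  pop <- simulate_wave(cfg)
  avg <- average_across_conditions(pop)

  # brute-force centroid oracle
  cent <- numeric(20)
  for (i in 1:20) cent[i] <- sum(avg[i, ] * pop$grid$times) / sum(avg[i, ])
  expect_equal(centroid_times(avg), cent, tolerance = 1e-12)

  slope <- stats::coef(stats::lm(cent ~ seq_len(20)))[2]
  expect_equal(unname(slope), 1, tolerance = 1e-8)
})

test_that("simulation is deterministic in the seed, amplitudes bounded", {
  cfg <- wave_config(n_neurons = 15, n_conditions = 10, onsets_ms = 100,
                     lag_ms = 10, seed = 7)
  a <- simulate_wave(cfg)
  b <- simulate_wave(cfg)
  expect_identical(a$rates, b$rates)

  cfg2 <- cfg; cfg2$seed <- 8L
  c2 <- simulate_wave(cfg2)
  expect_false(identical(a$rates, c2$rates))
  # a different seed moves amplitudes, never peak times
  expect_identical(apply(a$rates, c(1, 2), which.max),
                   apply(c2$rates, c(1, 2), which.max))

  # with on-grid peak times the peak value is the amplitude draw
  peaks <- apply(a$rates, c(1, 2), max)
  expect_true(all(peaks >= 0.2 & peaks < 1.2))
})

test_that("synchronous population shares peak times within groups", {
  cfg <- wave_config(n_neurons = 12, n_conditions = 9,
                     onsets_ms = c(50, 150, 200), seed = 2)
  pop <- simulate_synchronous(cfg)
  g <- pop$grid

  pk <- apply(pop$rates, c(1, 2), function(r) g$times[which.max(r)])
  # all neurons peak together within any one condition
  expect_true(all(apply(pk, 2, function(col) length(unique(col)) == 1L)))
  # between-group argmax differences equal the configured onset offsets
  expect_identical(pk[1, 4] - pk[1, 1], 100)
  expect_identical(pk[1, 7] - pk[1, 4], 50)

  # one group: every neuron's PETH is a scaling of a common time course
  one <- simulate_synchronous(wave_config(n_neurons = 6, n_conditions = 4,
                                          onsets_ms = 250, seed = 5))
  for (cc in 1:4) {
    m <- one$rates[, cc, ]
    expect_equal(qr(m)$rank, 1L)
  }
})

test_that("config validation rejects malformed partitions and parameters", {
  expect_error(wave_config(amplitude_range = c(1, 1)), "low < high")
  expect_error(wave_config(n_neurons = 0), "at least one")
  expect_error(wave_config(onsets_ms = c(50, 200),
                           condition_groups = list(1:60, 50:108)),
               "partition")
  # group blocks default to the printed contiguous splits
  cfg <- wave_config(onsets_ms = c(50, 200))
  expect_identical(cfg$condition_groups[[1]], 1:54)
  expect_identical(cfg$condition_groups[[2]], 55:108)
  cfg3 <- wave_config(onsets_ms = c(50, 150, 200))
  expect_identical(vapply(cfg3$condition_groups, length, 1L), c(36L, 36L, 36L))
})

test_that("populations round-trip through the CSV container", {
  pop <- simulate_wave(wave_config(n_neurons = 4, n_conditions = 3,
                                   onsets_ms = 100, lag_ms = 10, seed = 1))
  path <- file.path(tempdir(), "pop.csv")
  write_population_csv(pop, path)
  back <- read_population_csv(path)
  expect_equal(back$rates, pop$rates, tolerance = 1e-12)
  expect_identical(back$grid$times, pop$grid$times)
  expect_identical(back$neuron_ids, pop$neuron_ids)
  unlink(c(path, paste0(path, ".json")))
})
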