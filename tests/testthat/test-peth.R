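test_that("averaging across conditions is the arithmetic mean", {
  r <- array(runif(4 * 1 * 5), dim = c(4, 1, 5))
  # identical conditions: average equals any single condition
  rr <- array(0, dim = c(4, 3, 5))
  for (cc in 1:3) rr[, cc, ] <- r[, 1, ]
  pop <- make_pop(rr, grid = time_grid(0, 40, 10))
  expect_equal(unclass(average_across_conditions(pop))[, ],
               r[, 1, ], ignore_attr = TRUE)

  # conditions r and 3r average to 2r
  rr2 <- array(0, dim = c(4, 2, 5))
  rr2[, 1, ] <- r[, 1, ]; rr2[, 2, ] <- 3 * r[, 1, ]
  pop2 <- make_pop(rr2, grid = time_grid(0, 40, 10))
  expect_equal(average_across_conditions(pop2), 2 * r[, 1, ],
               ignore_attr = TRUE)
})

test_that("peak ordering sorts by peak time with stated tie-breaks", {
  times <- seq(0, 50, 10)
  bump <- function(tau) exp(-(times - tau)^2 / 50)
  sorted <- rbind(bump(0), bump(10), bump(30))
  attr(sorted, "times") <- times
  pk <- order_by_peak(sorted)
  expect_identical(attr(pk, "order"), 1:3)
  expect_identical(pk$rank, 1:3)
  expect_identical(pk$peak_ms, c(0, 10, 30))

  rev_mat <- sorted[3:1, ]
  attr(rev_mat, "times") <- times
  expect_identical(attr(order_by_peak(rev_mat), "order"), 3:1)

  # idempotence: reordering already-ordered data is the identity
  re <- sorted[attr(pk, "order"), ]
  attr(re, "times") <- times
  expect_identical(attr(order_by_peak(re), "order"), 1:3)

  # constant row: degenerate, peak at first grid time
  m <- rbind(bump(30), rep(2, 6))
  attr(m, "times") <- times
  pk2 <- order_by_peak(m)
  expect_true(pk2$degenerate[2])
  expect_identical(pk2$peak_ms[2], 0)

  # peak-time ties broken by original index (stable)
  m3 <- rbind(bump(20), bump(20))
  attr(m3, "times") <- times
  expect_identical(attr(order_by_peak(m3), "order"), 1:2)
})

test_that("one-grid-bin lag is recovered as the identity permutation", {
  cfg <- wave_config(n_neurons = 30, n_conditions = 8, onsets_ms = 50,
                     lag_ms = 10, seed = 4)
  pop <- simulate_wave(cfg)
  pk <- order_by_peak(average_across_conditions(pop))
  expect_identical(attr(pk, "order"), 1:30)

  # per-(neuron, condition) peak scatter tracks the true sequence
  sc <- peak_times(pop)
  expect_gte(cor(sc$neuron, sc$peak_ms, method = "spearman"), 0.99)
})

test_that("subpopulation splits use ceil-first contiguous allocation", {
  fake_pk <- function(n) {
    m <- matrix(stats::runif(n * 4), n)
    m[cbind(seq_len(n), rep_len(1:4, n))] <- 2   # distinct-ish peaks
    attr(m, "times") <- seq(0, 30, 10)
    order_by_peak(m)
  }
  expect_identical(split_subpopulations(fake_pk(218), 3)$sizes,
                   c(73L, 73L, 72L))
  expect_identical(split_subpopulations(fake_pk(6), 3)$sizes, c(2L, 2L, 2L))
  expect_identical(split_subpopulations(fake_pk(7), 3)$sizes, c(3L, 2L, 2L))
  expect_error(split_subpopulations(fake_pk(4), 9), "n_groups")

  # groups partition all neurons
  sp <- split_subpopulations(fake_pk(11), 3)
  expect_identical(sort(unlist(sp$members)), 1:11)
})

test_that("subpopulation averages are linear in the member PETHs", {
  times <- seq(0, 60, 10)
  b <- exp(-(times - 30)^2 / 50)
  rates <- array(0, dim = c(4, 2, 7))
  for (i in 1:4) for (cc in 1:2) rates[i, cc, ] <- b * cc
  pop <- make_pop(rates, grid = time_grid(0, 60, 10))
  pk <- order_by_peak(average_across_conditions(pop))
  sp <- split_subpopulations(pk, 2)
  sa <- subpopulation_averages(pop, sp)
  # identical members: the group average is the member PETH exactly
  expect_equal(sa[1, 1, ], b, tolerance = 1e-14)
  expect_equal(sa[2, 2, ], 2 * b, tolerance = 1e-14)
})

test_that("pairwise correlations decay with peak-time offset and are PSD", {
  times <- seq(-50, 550, 10)
  deltas <- seq(0, 120, 20)
  rates <- array(0, dim = c(length(deltas), 1, length(times)))
  # broad kernels keep neighbouring bumps overlapping over the whole
  # offset range, so the decay stays strict
  for (i in seq_along(deltas))
    rates[i, 1, ] <- exp(-(times - 200 - deltas[i])^2 / 5000)
  pop <- population_peth(rates, time_grid())
  cc <- pairwise_correlation(pop)

  expect_equal(diag(cc), rep(1, length(deltas)), ignore_attr = TRUE)
  expect_equal(cc, t(cc), tolerance = 1e-12)
  # correlation with neuron 1 strictly decreases as the offset grows
  expect_true(all(diff(cc[1, ]) < 0))
  # positive semidefinite up to numerical tolerance
  expect_gte(min(eigen(cc, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)

  # a zero-variance neuron yields NA with a warning
  rates2 <- rates; rates2[2, 1, ] <- 1
  pop2 <- population_peth(rates2, time_grid())
  expect_warning(cc2 <- pairwise_correlation(pop2), "zero-variance")
  expect_true(is.na(cc2[1, 2]))

  # anticorrelated patterns reach -1 (transformed scale population)
  r3 <- array(0, dim = c(2, 1, length(times)))
  r3[1, 1, ] <- sin(times / 50); r3[2, 1, ] <- -sin(times / 50)
  pop3 <- population_peth(r3, time_grid(), raw = FALSE)
  expect_equal(pairwise_correlation(pop3)[1, 2], -1, tolerance = 1e-12)
})

test_that("display normalization follows (x - mean)/max and is scale-free", {
  x <- c(1, 4, 2, 8, 5)
  y <- normalize_for_display(x)
  expect_equal(y, (x - mean(x)) / max(x), tolerance = 1e-14)
  expect_equal(max(y), (max(x) - mean(x)) / max(x), tolerance = 1e-14)
  expect_equal(normalize_for_display(10 * x), y, tolerance = 1e-14)
  expect_equal(normalize_for_display(rep(3, 5)), rep(0, 5))
  expect_error(normalize_for_display(c(-1, 0, -2)), "positive")
})
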