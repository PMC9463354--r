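test_that("oscillation index measures second-difference roughness", {
  expect_equal(oscillation_index(rep(3, 10)), 0)
  expect_equal(oscillation_index(seq(0, 9)), 0)
  # hand evaluation for (0, 1, 0, 1, 0): |second diffs| = 2, 2, 2
  expect_equal(oscillation_index(c(0, 1, 0, 1, 0)), 6 / 5)
  expect_equal(oscillation_index(uniform_curve(numeric(5), dt = 1)), 0)
  expect_error(oscillation_index(c(1, 2)), "length")
})

test_that("delay read-out takes the earliest maximum", {
  expect_equal(delay_from_residue(uniform_curve(c(5, 4, 3, 1), dt = 1.24)), 0)
  expect_equal(delay_from_residue(uniform_curve(c(0, 1, 5, 2), dt = 2)), 4)
  expect_equal(delay_from_residue(uniform_curve(c(0, 1, 3, 3, 3, 1), dt = 1)),
               2)
})

test_that("identity deconvolution returns a discrete unit-area delta", {
  grid <- std_grid()
  aif <- std_aif(grid)
  fit <- osvd(aif, aif, osvd_settings(oi_threshold = 1e6))
  expect_equal(fit$cbf, 1 / grid$dt, tolerance = 1e-6)
  expect_equal(sum(fit$impulse$values) * grid$dt, 1, tolerance = 1e-6)
  expect_error(osvd(aif, uniform_curve(numeric(162), dt = 1.24)),
               "all zero")
})

test_that("noiseless oSVD recovers CBF at a generous threshold", {
  grid <- std_grid()
  aif <- std_aif(grid)
  R <- gamma_residue(1, 12, grid)
  ctc <- forward_model(aif, R, 20 / 6000)
  fit <- osvd(ctc, aif, osvd_settings(oi_threshold = 0.035))
  expect_gt(fit$cbf * 6000 / 20, 0.9)
  expect_lt(fit$cbf * 6000 / 20, 1.1)
})

test_that("the block-circulant formulation is delay-insensitive", {
  grid <- std_grid()
  aif <- std_aif(grid)
  R <- gamma_residue(1, 8, grid)
  base <- osvd(forward_model(aif, R, 0.01), aif,
               osvd_settings(oi_threshold = 0.035))
  for (k in c(2, 5)) {
    delayed <- forward_model(shift_curve(aif, k * grid$dt), R, 0.01)
    fit <- osvd(delayed, aif, osvd_settings(oi_threshold = 0.035))
    expect_lt(abs(fit$cbf / base$cbf - 1), 0.01)
    # the delay read-out tracks the shift
    expect_equal(fit$delay, k * grid$dt, tolerance = grid$dt)
  }
})

test_that("an infinite OI threshold reduces to the unregularized solve", {
  grid <- uniform_curve(numeric(40), dt = 1.24)
  aif <- gamma_variate_aif(grid, t0 = 5)
  ctc <- forward_model(aif, gamma_residue(1, 6, grid), 0.01)
  fit <- osvd(ctc, aif, osvd_settings(oi_threshold = Inf))
  expect_equal(fit$threshold_frac, 0)
  # independent oracle: direct pseudo-inverse of the circulant system
  n2 <- 80
  ca <- c(aif$values, numeric(40))
  A <- matrix(0, n2, n2)
  for (i in 1:n2) for (j in 1:n2) A[i, j] <- 1.24 * ca[((i - j) %% n2) + 1]
  r <- as.numeric(MASS::ginv(A) %*% c(ctc$values, numeric(40)))
  expect_equal(fit$impulse$values, r, tolerance = 1e-6)
})

test_that("noisy deconvolution regularizes until the OI criterion holds", {
  grid <- std_grid()
  aif <- std_aif(grid)
  ctc <- clean_ctc(40)
  set.seed(1)
  noisy <- uniform_curve(ctc$values + rnorm(162, sd = 0.02 * max(ctc$values)),
                         dt = 1.24)
  fit <- osvd(noisy, aif, osvd_settings(oi_threshold = 0.035))
  expect_lte(fit$oi, 0.035)
  expect_gt(fit$threshold_frac, 0)
})
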