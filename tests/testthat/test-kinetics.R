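test_that("discrete convolution matches a brute-force oracle and its algebra", {
  f <- uniform_curve(c(1, 3, 2, 4), dt = 0.5)
  g <- uniform_curve(c(2, 0.5, 1, 0.25), dt = 0.5)
  out <- convolve_uniform(f, g)
  # independent double-loop oracle
  oracle <- sapply(1:4, function(k) {
    acc <- 0
    for (j in 1:k) acc <- acc + f$values[k - j + 1] * g$values[j]
    acc * 0.5
  })
  expect_equal(out$values, oracle, tolerance = 1e-14)

  # identity element: discrete delta of unit area
  delta <- uniform_curve(c(1 / f$dt, 0, 0, 0), dt = f$dt)
  expect_equal(convolve_uniform(f, delta)$values, f$values, tolerance = 1e-12)

  expect_error(convolve_uniform(f, uniform_curve(1:4, dt = 0.7)), "dt")
})

test_that("convolution conserves area and start times add", {
  grid <- std_grid()
  aif <- std_aif(grid)
  for (mtt in c(4, 24)) {
    R <- gamma_residue(1, mtt, grid)
    cv <- convolve_uniform(aif, R)
    a_conv <- sum(cv$values) * grid$dt
    a_prod <- (sum(aif$values) * grid$dt) * (sum(R$values) * grid$dt)
    expect_equal(a_conv, a_prod, tolerance = 1e-3)
  }
  f <- uniform_curve(1:4, dt = 1, t0 = 2)
  g <- uniform_curve(1:4, dt = 1, t0 = 5)
  expect_equal(convolve_uniform(f, g)$t0, 7)
})

test_that("shift_curve handles zero, integer and sub-sample shifts", {
  x <- uniform_curve(c(0, 0, 1, 4, 2, 1, 0.5, 0), dt = 1)
  expect_equal(shift_curve(x, 0)$values, x$values, tolerance = 1e-12)
  s2 <- shift_curve(x, 2)
  expect_equal(s2$values[3:8], x$values[1:6], tolerance = 1e-9)
  expect_equal(s2$values[1:2], c(0, 0))

  ramp <- uniform_curve(0:9, dt = 1)
  half <- shift_curve(ramp, 0.5)
  # cubic spline is exact on a linear ramp away from the zero-filled edge
  expect_equal(half$values[3:9], (0:9)[3:9] - 0.5, tolerance = 1e-8)

  expect_warning(shift_curve(x, 100), "record length")
  expect_equal(suppressWarnings(shift_curve(x, 100))$values, rep(0, 8))
})

test_that("shift_curve round-trips away from the boundary", {
  grid <- std_grid()
  aif <- std_aif(grid)
  back <- shift_curve(shift_curve(aif, 3.7), -3.7)
  inner <- 5:150
  # spline interpolation error concentrates at the bolus-arrival kink; the
  # bound is ~0.25% of the AIF peak
  expect_lt(max(abs(back$values[inner] - aif$values[inner])), 0.02)
})

test_that("gamma transport kernel has unit area and peaks at p", {
  grid <- std_grid()
  for (sp in list(c(0.5, 5), c(1, 3), c(2, 1))) {
    k <- gamma_vtf(sp[1], sp[2], grid)
    expect_equal(sum(k$values) * grid$dt, 1, tolerance = 1e-12)
  }
  # p = 0 reduces to an exponential with rate s
  k0 <- gamma_vtf(0.8, 0, grid)
  ex <- exp(-0.8 * curve_time(grid))
  ex <- ex / (sum(ex) * grid$dt)
  expect_equal(k0$values, ex, tolerance = 1e-10)
  # s = 1, p = 3: discrete argmax within one step of 3 s
  k1 <- gamma_vtf(1, 3, grid)
  expect_lt(abs(curve_time(grid)[which.max(k1$values)] - 3), grid$dt + 1e-9)
  expect_error(gamma_vtf(-1, 3, grid), "positive")
})

test_that("forward model composes shift, dispersion and convolution", {
  grid <- std_grid()
  aif <- std_aif(grid)
  R <- gamma_residue(1, 8, grid)
  expect_equal(forward_model(aif, R, cbf = 0)$values, rep(0, 162))

  # plain call is exactly the no-delay, no-dispersion case
  expect_identical(forward_model(aif, R, 0.01)$values,
                   forward_model(aif, R, 0.01, delta = NULL, vtf = NULL)$values)

  # delay commutes with convolution
  d1 <- forward_model(aif, R, 0.01, delta = 3)
  d2 <- forward_model(shift_curve(aif, 3), R, 0.01)
  expect_equal(d1$values, d2$values, tolerance = 1e-12)

  # unit-area dispersion preserves the curve integral (CBV)
  plain <- forward_model(aif, R, 0.01)
  disp <- forward_model(aif, R, 0.01, vtf = c(log(2), log(2)))
  expect_equal(cbv_from_curves(disp, aif), cbv_from_curves(plain, aif),
               tolerance = 1e-6)
})

test_that("MTT and CBV integrals follow tracer-kinetic identities", {
  box <- uniform_curve(c(rep(1, 11), rep(0, 20)), dt = 1)
  expect_equal(mtt_from_residue(box), 10.5, tolerance = 1e-12)  # trapezoid edge
  dense <- uniform_curve(numeric(24000), dt = 0.005)
  expect_equal(mtt_from_residue(gamma_residue(1, 12, dense)), 12,
               tolerance = 1e-3)
  expect_equal(mtt_from_residue(uniform_curve(numeric(10) + 0, dt = 1)), 0)

  grid <- std_grid()
  aif <- std_aif(grid)
  expect_equal(cbv_from_curves(aif, aif, kappa = 1), 1)
  ctc <- clean_ctc(60)
  # discrete identity: with left-rectangle convolution the curve-area ratio
  # equals CBF times the rectangle-rule area of R (MTT + dt/2 to first order)
  R <- gamma_residue(1, 4, grid)
  expect_equal(cbv_from_curves(ctc, aif),
               0.01 * sum(R$values) * grid$dt, tolerance = 2e-3)
  expect_error(cbv_from_curves(ctc, uniform_curve(numeric(162), dt = 1.24)),
               "positive")
})
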