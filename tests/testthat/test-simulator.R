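test_that("gamma-variate AIF matches its closed form", {
  grid <- std_grid()
  aif <- gamma_variate_aif(grid)
  tt <- curve_time(grid)
  expect_equal(aif$values[tt <= 20], rep(0, sum(tt <= 20)))
  # value at t0 + 3 s (use a grid that hits it exactly)
  g2 <- uniform_curve(numeric(100), dt = 0.5)
  a2 <- gamma_variate_aif(g2)
  expect_equal(a2$values[curve_time(g2) == 23], 27 * exp(-2))
  # continuous peak at t0 + b*c = 24.5 s; discrete argmax within one TR
  expect_lt(abs(tt[which.max(aif$values)] - 24.5), 1.24)
})

test_that("gamma-family residue functions follow the tail-probability form", {
  grid <- std_grid()
  for (mtt in c(4, 12)) {
    R1 <- gamma_residue(1, mtt, grid)
    expect_equal(R1$values, exp(-curve_time(grid) / mtt), tolerance = 1e-12)
  }
  for (lam in c(1, 5, 100)) {
    R <- gamma_residue(lam, 12, grid)
    expect_equal(R$values[1], 1)
    expect_true(all(diff(R$values) <= 0))
    expect_equal(mtt_from_residue(R), 12, tolerance = 2e-3)
  }
  # independent oracle: numerical integration of the gamma-density tail
  set.seed(3)
  for (i in 1:20) {
    lam <- runif(1, 0.5, 50); mtt <- runif(1, 3, 24); t <- runif(1, 0, 40)
    beta <- mtt / lam
    tail <- integrate(function(x) dgamma(x, shape = lam, scale = beta),
                      lower = t, upper = Inf, rel.tol = 1e-10)$value
    g <- uniform_curve(numeric(2), dt = max(t, 1e-3))
    expect_equal(gamma_residue(lam, mtt, g)$values[2], tail,
                 tolerance = 1e-6)
  }
})

test_that("signal-model constants are calibrated to the stated peak drops", {
  grid <- std_grid()
  xi <- calibrate_xi(grid)
  aif <- std_aif(grid)
  ref_ctc <- clean_ctc(60)
  s_t <- concentration_to_signal(ref_ctc, 100, 0.029, xi$xi_tissue)
  s_a <- concentration_to_signal(aif, 100, 0.029, xi$xi_aif)
  expect_equal(min(s_t$values), 60, tolerance = 1e-9)
  expect_equal(min(s_a$values), 40, tolerance = 1e-9)
  # closed form: doubling the reference peak concentration halves xi
  expect_equal(xi$xi_aif, -log(0.4) / (0.029 * max(aif$values)))
})

test_that("Rician noise has the documented moments", {
  s <- uniform_curve(rep(100, 2), dt = 1)
  expect_identical(add_rician_noise(s, Inf)$values, s$values)

  set.seed(1234)
  n <- 1e5
  draws <- replicate(2, {
    big <- uniform_curve(rep(100, n), dt = 1)
    add_rician_noise(big, snr = 20, s0 = 100)$values
  })
  m <- mean(draws)
  # Rician mean at baseline: S0 * (1 + 1/(2 SNR^2)) to second order
  expect_equal(m, 100 * (1 + 1 / (2 * 400)), tolerance = 5e-4)
  expect_equal(sd(draws), 5, tolerance = 0.02)
})

test_that("the exponential dispersion kernel is a unit-area exponential", {
  grid <- std_grid()
  for (th in c(1.5, 3, 4.5)) {
    k <- exponential_dispersion_kernel(th, grid)
    expect_equal(sum(k$values) * grid$dt, 1, tolerance = 1e-12)
  }
  fine <- uniform_curve(numeric(4000), dt = 0.05)
  k <- exponential_dispersion_kernel(1.5, fine)
  expect_equal(sum(curve_time(fine) * k$values) * 0.05, 1.5,
               tolerance = 0.03)
  # theta -> 0 approaches a discrete delta
  k0 <- exponential_dispersion_kernel(1e-4, grid)
  expect_gt(k0$values[1] * grid$dt, 0.999)
})

test_that("high-resolution delays equal an analytic bolus-arrival shift", {
  grid <- std_grid()
  expect_equal(apply_delay_highres(grid, 0)$values,
               gamma_variate_aif(grid)$values, tolerance = 1e-5)
  for (d in c(1, 6)) {
    expect_equal(apply_delay_highres(grid, d)$values,
                 gamma_variate_aif(grid, t0 = 20 + d)$values,
                 tolerance = 1e-4)
  }
})

test_that("simulated datasets are deterministic and prefix-consistent", {
  cfg <- sim_config(n_reps = 2, cbf_grid = c(20, 60), seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$voxels[[1]]$ctc$values, d2$voxels[[1]]$ctc$values)
  expect_identical(d1$truth, d2$truth)

  cfg4 <- sim_config(n_reps = 4, cbf_grid = c(20, 60), seed = 77)
  d4 <- simulate_dataset(cfg4)
  # replicates 1..2 of each CBF level coincide with the smaller run
  for (ci in 1:2) for (rep in 1:2) {
    v2 <- which(d1$truth$cbf_index == ci & d1$truth$rep == rep)
    v4 <- which(d4$truth$cbf_index == ci & d4$truth$rep == rep)
    expect_identical(d1$voxels[[v2]]$ctc$values, d4$voxels[[v4]]$ctc$values)
  }
})

test_that("the two CBV grids share one MTT multiset and infinite SNR is clean", {
  cfg_a <- sim_config(cbv = 0.04, cbf_grid = seq(10, 70, 10), n_reps = 1)
  cfg_b <- sim_config(cbv = 0.02, cbf_grid = seq(5, 35, 5), n_reps = 1)
  mtt_a <- sort(unique(simulate_dataset(cfg_a)$truth$mtt))
  mtt_b <- sort(unique(simulate_dataset(cfg_b)$truth$mtt))
  expect_equal(mtt_a, mtt_b, tolerance = 1e-12)
  expect_equal(range(mtt_a), c(3.43, 24), tolerance = 1e-3)

  cfg_inf <- sim_config(snr = Inf, n_reps = 1, cbf_grid = 60)
  ds <- simulate_dataset(cfg_inf)
  clean <- forward_model(ds$aif_clean,
                         ds$voxels[[1]]$residue_truth, 0.01)
  expect_equal(ds$voxels[[1]]$ctc$values, clean$values, tolerance = 1e-9)
  expect_equal(ds$voxels[[1]]$aif$values, ds$aif_clean$values,
               tolerance = 1e-9)
})

test_that("noiseless curve areas satisfy the volume identity", {
  for (lam in c(1, 100)) for (disp in list(list(kind = "none"),
                                           list(kind = "exponential",
                                                theta = 3))) {
    cfg <- sim_config(snr = Inf, lam = lam, n_reps = 1, cbf_grid = c(20, 60),
                      dispersion = disp)
    ds <- simulate_dataset(cfg)
    for (v in seq_along(ds$voxels)) {
      cbv <- cbv_from_curves(ds$voxels[[v]]$ctc, ds$aif_clean)
      # rectangle-rule discrete identity: area ratio = CBF x rect-area of R
      pred <- ds$truth$cbf[v] * sum(ds$voxels[[v]]$residue_truth$values) *
        ds$grid$dt
      expect_equal(cbv, pred, tolerance = 5e-3)
    }
  }
})

test_that("simulation configs reject invalid kernels and values", {
  expect_error(sim_config(snr = -2), "snr")
  expect_error(sim_config(cbv = 1.2), "cbv")
  expect_error(sim_config(dispersion = list(kind = "lorentzian")),
               "unknown dispersion")
})
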