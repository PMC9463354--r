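test_that("negative log posterior validates input and prices priors", {
  grid <- std_grid()
  aif <- std_aif(grid)
  ctc <- clean_ctc(30)
  pr <- bzd_priors()
  v <- bzd_variant("plain")
  th <- c(8, 0.5, 2, 0.2, 15, 0.005)

  expect_error(neg_log_posterior(c(th, 1), ctc, aif, pr, v), "length")
  expect_error(neg_log_posterior(replace(th, 1, NA), ctc, aif, pr, v),
               "finite")

  # doubling a parameter's distance from its prior mean (data term frozen by
  # moving the prior mean instead of the parameter) quadruples the prior term
  base <- neg_log_posterior(th, ctc, aif, pr, v)
  pr1 <- bzd_priors(cp_mean = c(8 - 4, 0.5, 2, 0.2, 15))
  pr2 <- bzd_priors(cp_mean = c(8 - 8, 0.5, 2, 0.2, 15))
  d1 <- neg_log_posterior(th, ctc, aif, pr1, v) - base
  d2 <- neg_log_posterior(th, ctc, aif, pr2, v) - base
  expect_equal(d2 / d1, 4, tolerance = 1e-9)

  # infeasible control points cost at least the documented penalty
  th_bad <- replace(th, 2, 1.5)
  expect_gt(neg_log_posterior(th_bad, ctc, aif, pr, v),
            neg_log_posterior(th, ctc, aif, pr, v) + 1e6 * 0.25 * 0.9)

  # finite everywhere, including degenerate p3x
  expect_true(is.finite(neg_log_posterior(replace(th, 5, -2), ctc, aif,
                                          pr, v)))
})

test_that("noiseless data sits at a local minimum of the data term", {
  grid <- std_grid()
  aif <- std_aif(grid)
  ctc <- clean_ctc(30)
  pr <- bzd_priors(cp_sd = c(8, 1, 4, 1, 100) * 1e6, cbf_sd = 1e12)
  v <- bzd_variant("plain")
  fit <- bzd(ctc, aif, priors = pr)
  th <- coef(fit)
  f0 <- neg_log_posterior(th, ctc, aif, pr, v)
  for (i in seq_along(th)) {
    for (eps in c(-1, 1) * 0.05 * pmax(abs(th[i]), 0.01)) {
      expect_gte(neg_log_posterior(replace(th, i, th[i] + eps),
                                   ctc, aif, pr, v), f0 - 1e-6)
    }
  }
})

test_that("default priors read the delay prior mean off the peaks", {
  grid <- std_grid()
  aif <- std_aif(grid)
  ctc_late <- shift_curve(aif, 3 * 1.24)
  pr <- default_priors(aif, ctc_late, bzd_variant("delay"))
  expect_equal(pr$delay_mean, 3 * 1.24, tolerance = 1e-9)
  expect_equal(pr$delay_sd, 5)

  ctc_early <- shift_curve(aif, -2 * 1.24)
  pr2 <- default_priors(aif, ctc_early, bzd_variant("delay"))
  expect_equal(pr2$delay_mean, 0)

  expect_equal(pr$cp_mean, c(8, 0.5, 2, 0.2, 15))
  expect_equal(pr$cp_sd, c(8, 1, 4, 1, 100))
  expect_equal(pr$cbf_mean, 0.01)
  expect_equal(pr$vtf_mean, c(log(2), log(2)))

  flat <- uniform_curve(rep(1, 162), dt = 1.24)
  expect_warning(default_priors(flat, flat, bzd_variant("delay")), "flat")
})

test_that("model variants size their parameter vectors correctly", {
  expect_length(bzd_variant("plain")$par_names, 6)
  expect_length(bzd_variant("delay")$par_names, 7)
  expect_length(bzd_variant("disp")$par_names, 8)
  expect_length(bzd_variant("delay-disp")$par_names, 9)
  expect_error(bzd_variant("tikhonov"))
})

test_that("noiseless fits recover CBF and the residue shape", {
  grid <- std_grid()
  aif <- std_aif(grid)
  for (cbf_clin in c(10, 30, 60)) {
    truth_R <- gamma_residue(1, 0.04 / (cbf_clin / 6000), grid)
    fit <- bzd(forward_model(aif, truth_R, cbf_clin / 6000), aif)
    expect_lt(abs(fit$cbf * 6000 / cbf_clin - 1), 0.03)
    expect_lt(residue_rmse(fit$residue, truth_R), 0.02)
    # returned residue is anchored and non-increasing
    expect_equal(fit$residue$values[1], max(fit$residue$values))
    expect_true(all(diff(fit$residue$values) <= 1e-6))
  }
})

test_that("the delay variant recovers a 6 s shift and tolerates none", {
  grid <- std_grid()
  aif <- std_aif(grid)
  R <- gamma_residue(1, 4, grid)
  ctc6 <- forward_model(apply_delay_highres(grid, 6), R, 0.01)
  fit6 <- bzd(ctc6, aif, variant = "delay")
  expect_lt(abs(fit6$delay - 6), 0.5)

  ctc0 <- forward_model(aif, R, 0.01)
  plain <- bzd(ctc0, aif)
  with_delay <- bzd(ctc0, aif, variant = "delay")
  expect_lt(abs(with_delay$cbf / plain$cbf - 1), 0.05)
})

test_that("degenerate input yields a near-zero flow estimate", {
  grid <- std_grid()
  aif <- std_aif(grid)
  fit <- bzd(uniform_curve(numeric(162), dt = 1.24), aif)
  expect_lt(fit$cbf * 6000, 1e-3)
  expect_true(fit$converged)
})

test_that("fit methods expose the standard modelling interface", {
  grid <- std_grid()
  aif <- std_aif(grid)
  ctc <- clean_ctc(40)
  fit <- bzd(ctc, aif)
  expect_s3_class(fit, "bzd")
  expect_named(coef(fit), c("p1x", "p1y", "p2x", "p2y", "p3x", "cbf"))
  expect_equal(fitted(fit)$values + residuals(fit), ctc$values)
  expect_equal(predict(fit)$values, fitted(fit)$values)
  s <- summary(fit)
  expect_s3_class(s, "summary.bzd")
  # curve-area CBV carries the rectangle-rule dt/2 inflation
  expect_equal(s$cbv_percent, 4, tolerance = 0.15)
  expect_output(print(fit), "CBF")
  # predict with a replacement AIF rescales the prediction
  expect_equal(predict(fit, aif = uniform_curve(2 * aif$values,
                                                dt = 1.24))$values,
               2 * fitted(fit)$values, tolerance = 1e-10)
})
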