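# Structural model components: exposure, onset, mixture baseline.

test_that("steady-state AUC follows dose * N / CL", {
  expect_equal(compute_auc_ss(cl = 7, n_doses = 0), 0)     # placebo
  expect_equal(compute_auc_ss(cl = 10, n_doses = 2), 25)
  expect_equal(compute_auc_ss(cl = 10, n_doses = 1), 12.5)
  expect_error(compute_auc_ss(cl = -1, n_doses = 1), "cl")
  expect_error(compute_auc_ss(cl = 10, n_doses = 3), "n_doses")
  # placebo tolerates any clearance value
  expect_equal(compute_auc_ss(cl = -1, n_doses = 0), 0)
})

test_that("exposure multiplier matches the published halving exposures", {
  # each additional 27 ng.h/mL of AUCss halves lambda at beta = -0.0256
  expect_equal(exposure_multiplier(log(2) / 0.0256, beta = -0.0256), 0.5)
  expect_equal(exposure_multiplier(27.07, beta = -0.0256), 0.5,
               tolerance = 1e-3)
  expect_equal(exposure_multiplier(47.15, beta = -0.0147), 0.5,
               tolerance = 1e-3)
  expect_equal(exposure_multiplier(0, beta = -0.5), 1)

  # Emax form limits
  expect_equal(exposure_multiplier(1e12, form = "emax", emax = 1, ec50 = 10),
               0, tolerance = 1e-10)
  expect_equal(exposure_multiplier(10, form = "emax", emax = 0.8, ec50 = 10),
               1 - 0.8 / 2)

  # monotone non-increasing in AUC for both forms
  auc <- seq(0, 60, by = 0.5)
  expect_true(all(diff(exposure_multiplier(auc, beta = -0.02)) < 0))
  em <- exposure_multiplier(auc, form = "emax", emax = 0.9, ec50 = 12)
  expect_true(all(diff(em) < 0))
  expect_true(all(em > 0 & em <= 1))
})

test_that("onset multiplier is a first-order half-life curve", {
  expect_equal(onset_multiplier(0, 115), 0)
  expect_equal(onset_multiplier(115, 115), 0.5)
  expect_equal(onset_multiplier(10 * 115, 115), 1 - 2^-10)
  # truncated constant 0.69 supported as a config switch
  expect_equal(onset_multiplier(115, 115, rate_const = 0.69),
               1 - exp(-0.69))
  tt <- seq(0, 2000, by = 10)
  on <- onset_multiplier(tt, 115)
  expect_true(all(diff(on) > 0))
  expect_true(all(on >= 0 & on < 1))
  expect_error(onset_multiplier(-1, 115), "t")
})

test_that("zero-inflation probability is logistic in exposure", {
  expect_equal(p0_at_exposure(c(0, 10, 50), p0_intercept = 0), rep(0.5, 3))
  expect_equal(p0_at_exposure(0, stats::qlogis(0.596)), 0.596)
  expect_equal(p0_at_exposure(30, stats::qlogis(0.596), gamma = 0.0163),
               stats::plogis(stats::qlogis(0.596) + 0.489))
})

test_that("lambda trajectories combine baseline, exposure and onset", {
  p <- list(beta = -0.0256, t_half = 115)
  # placebo: mean never moves off baseline
  expect_equal(lambda_trajectory(0.48, auc = rep(0, 4),
                                 t = rep(0, 4), p),
               rep(0.48, 4))
  # full onset at large t: 0.48 * exp(-0.768)
  expect_equal(lambda_trajectory(0.48, auc = 30, t = 1e9, p),
               0.48 * exp(-0.0256 * 30), tolerance = 1e-9)
  # T2 mode: proportional to interval length, no onset
  expect_equal(lambda_trajectory(0.0066, auc = 0, t = 0,
                                 list(beta = -0.0147), endpoint = "t2",
                                 interval_days = 168),
               0.0066 * 168)
  expect_error(lambda_trajectory(0.0066, auc = 0, t = 0,
                                 list(beta = -0.0147), endpoint = "t2"),
               "interval_days")
})

test_that("mixture baseline draws respect subpopulation structure", {
  mix <- final_params("gd")
  d <- withr::with_seed(5, draw_baseline_mixture(1e5, mix))
  expect_true(all(d$Y %in% 0:1))
  # Bernoulli mean theta within 4 MC SE
  se <- sqrt(mix$theta * (1 - mix$theta) / 1e5)
  expect_lt(abs(mean(d$Y) - mix$theta), 4 * se)
  # low subpopulation is a point mass at mu1 (omega2_low = 0)
  expect_true(all(d$lambda0[d$Y == 1] == mix$mu1))
  # degenerate high-activity variance -> exactly mu2
  mix0 <- mix; mix0$sigma2 <- 0
  d0 <- withr::with_seed(6, draw_baseline_mixture(1000, mix0))
  expect_true(all(d0$lambda0[d0$Y == 0] == mix$R * mix$mu1))
  # median of the high subpopulation is mu2 (lognormal parameterized by
  # log-median)
  expect_equal(stats::median(d$lambda0[d$Y == 0]), mix$R * mix$mu1,
               tolerance = 0.05)
})

test_that("weighted baseline mean and CV conventions", {
  gd <- final_params("gd")
  expect_equal(population_mean_baseline(gd),
               gd$theta * gd$mu1 + (1 - gd$theta) * gd$R * gd$mu1)
  expect_equal(population_mean_baseline(list(theta = 1, mu1 = 0.4, R = 3)),
               0.4)
  # mu2 / mu1 equals R exactly
  expect_equal((gd$R * gd$mu1) / gd$mu1, gd$R)

  expect_equal(cv_from_log_variance(0), 0)
  expect_equal(round(cv_from_log_variance(1.25)), 112)
  expect_equal(round(cv_from_log_variance(1.712)), 131)
  expect_error(cv_from_log_variance(-1), "var")
})
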