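# Synthetic trial generator and dataset I/O.

test_that("clearance simulator gives the intended exposure ordering", {
  expect_equal(simulate_clearance(10, cl_geomean = 8.5, cl_logsd = 0),
               rep(8.5, 10))
  cl <- withr::with_seed(1, simulate_clearance(1e5))
  auc_q2w <- compute_auc_ss(cl, 2)
  auc_q4w <- compute_auc_ss(cl, 1)
  expect_equal(stats::median(auc_q2w) / stats::median(auc_q4w), 2)
  # defaults center q4w near ~15 and q2w near ~30 ng.h/mL
  expect_equal(stats::median(auc_q4w), 125 / 8.5, tolerance = 0.02)
  expect_identical(withr::with_seed(4, simulate_clearance(100)),
                   withr::with_seed(4, simulate_clearance(100)))
})

test_that("default design reproduces the analyzed cohort structure", {
  dat <- simulate_trial(endpoint = "gd", seed = 2)
  expect_equal(length(unique(dat$subject_id)), 1505)
  tr <- attr(dat, "truth")
  expect_equal(as.vector(table(tr$arm)[c("placebo", "q2w", "q4w")]),
               c(497L, 510L, 498L))

  # baseline MRI precedes dosing in every arm
  b <- dat[dat$visit_day == 0, ]
  expect_true(all(b$auc_ss == 0 & b$t_active_days == 0))

  # placebo rows stay unexposed through week 48
  plc_ids <- tr$subject_id[tr$arm == "placebo"]
  yr1 <- dat[dat$subject_id %in% plc_ids & dat$visit_day <= 336, ]
  expect_true(all(yr1$auc_ss == 0 & yr1$period_arm == "placebo"))

  # re-randomized placebo restarts t_active at the switch
  yr2 <- dat[dat$subject_id %in% plc_ids & dat$visit_day == 672, ]
  expect_true(all(yr2$t_active_days == 336))
  expect_true(all(yr2$auc_ss > 0))
  expect_true(all(yr2$period_arm %in% c("q2w", "q4w")))
  # ~1:1 split of re-randomized placebo
  expect_equal(mean(yr2$period_arm == "q2w"), 0.5, tolerance = 0.1)

  # active arms: AUC fixed from the first post-baseline visit, t = visit day
  act <- dat[!dat$subject_id %in% plc_ids & dat$visit_day > 0, ]
  expect_true(all(act$t_active_days == act$visit_day))
  expect_true(all(act$auc_ss > 0))

  # dropout censors trailing visits only
  expect_true(all(dat$count >= 0 & dat$count == floor(dat$count)))
  n_vis <- table(dat$subject_id)
  expect_true(all(n_vis[as.character(
    tr$subject_id[!is.na(tr$drop_day)])] < 4))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_trial(small_design(50), endpoint = "gd", seed = 99)
  b <- simulate_trial(small_design(50), endpoint = "gd", seed = 99)
  expect_identical(a, b)
  c <- simulate_trial(small_design(50), endpoint = "gd", seed = 100)
  expect_false(identical(a$count, c$count))
})

test_that("T2 datasets are interval-based", {
  dat <- simulate_trial(small_design(80), endpoint = "t2", seed = 3)
  expect_true(all(dat$visit_day %in% c(168, 336, 672)))
  expect_equal(unique(dat$interval_days[dat$visit_day == 672]), 336)
  expect_equal(unique(dat$interval_days[dat$visit_day <= 336]), 168)
  # final interval of an untreated-year-1 placebo subject is exposed
  tr <- attr(dat, "truth")
  plc <- dat$subject_id %in% tr$subject_id[tr$arm == "placebo"]
  expect_true(all(dat$auc_ss[plc & dat$visit_day <= 336] == 0))
  expect_true(all(dat$auc_ss[plc & dat$visit_day == 672] > 0))
})

test_that("simulated placebo moments match the analytic mixture moments", {
  # large placebo-only arm, no dropout: E[count] =
  # theta*mu1 + (1-theta)*mu2*exp(sigma2/2) by the law of total expectation
  p <- final_params("gd")
  des <- trial_design(arm_sizes = c(placebo = 10000, q2w = 2, q4w = 2),
                      year1_dropout = c(placebo = 0, q2w = 0, q4w = 0),
                      year2_dropout = c(q2w = 0, q4w = 0))
  dat <- simulate_trial(des, endpoint = "gd", seed = 8)
  tr <- attr(dat, "truth")
  # placebo subjects are re-randomized to active drug at week 48, so only
  # their unexposed rows (through week 48) reflect the baseline mixture
  plc <- dat[dat$subject_id %in% tr$subject_id[tr$arm == "placebo"] &
               dat$visit_day <= 336, ]
  m_analytic <- p$theta * p$mu1 +
    (1 - p$theta) * p$R * p$mu1 * exp(p$sigma2 / 2)
  se <- stats::sd(plc$count) / sqrt(nrow(plc))
  expect_lt(abs(mean(plc$count) - m_analytic), 4 * se)
})

test_that("a null exposure effect leaves arms exchangeable", {
  p0 <- final_params("gd"); p0$beta <- 0
  dat <- simulate_trial(small_design(700), p0, endpoint = "gd", seed = 12)
  tr <- attr(dat, "truth")
  arm_of <- tr$arm[match(dat$subject_id, tr$subject_id)]
  wk96 <- dat$visit_day == 672
  m <- tapply(dat$count[wk96], arm_of[wk96], mean)
  s <- tapply(dat$count[wk96], arm_of[wk96], stats::sd)
  n <- tapply(dat$count[wk96], arm_of[wk96], length)
  se <- sqrt(s["placebo"]^2 / n["placebo"] + s["q2w"]^2 / n["q2w"])
  expect_lt(abs(m["placebo"] - m["q2w"]), 4 * se)
})

test_that("dataset round trips through CSV and is validated on the way", {
  dat <- simulate_trial(small_design(30), endpoint = "gd", seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_lesion_data(dat, path)
  back <- read_lesion_data(path)
  expect_equal(back, dat[names(back)], ignore_attr = TRUE)

  bad <- dat; bad$count <- NULL
  expect_error(validate_dataset(bad), "count")
  bad2 <- dat[, setdiff(names(dat), "auc_ss")]
  expect_error(validate_dataset(bad2), "auc_ss")
  bad3 <- dat; bad3$count[7] <- -2
  expect_error(validate_dataset(bad3), "row\\(s\\) 7")
})
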