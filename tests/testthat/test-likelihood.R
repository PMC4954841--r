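# Likelihood engine: conditional, pooled, Laplace and mixture marginals.

gd5 <- model_spec("M5", "gd")
gd_truth <- final_params("gd")

test_that("conditional log-likelihood sums independent visit terms", {
  spec1 <- model_spec("M1", "gd")
  p <- list(lam0 = 1, beta = 0, t_half = 115)
  s1 <- make_subject(0)
  expect_equal(subject_conditional_loglik(s1, 1, p, spec1), -1)
  s2 <- make_subject(c(0, 0))
  expect_equal(subject_conditional_loglik(s2, 1, p, spec1), -2)

  # NB term-by-term oracle on a placebo subject
  s4 <- make_subject(c(0, 2, 0, 1))
  spec3 <- model_spec("M3", "gd")
  p3 <- list(lam0 = 1, beta = -0.02, ovdp = 0.5)
  expect_equal(subject_conditional_loglik(s4, 1, p3, spec3),
               sum(nb_logpmf(c(0, 2, 0, 1), 1, 0.5)))
  # mixture subpopulation dispersion selection
  expect_equal(subject_conditional_loglik(s4, 1, gd_truth, gd5, "low"),
               sum(nb_logpmf(c(0, 2, 0, 1), 1, gd_truth$ovdp_low)))
})

test_that("pooled likelihood doubles when the dataset is duplicated", {
  dat <- pooled_dataset(20, 3, lam = 1.2, seed = 7)
  spec1 <- model_spec("M1", "gd")
  p <- list(lam0 = 0.9, beta = -0.01, t_half = 100)
  l1 <- pooled_loglik(dat, p, spec1)
  dat2 <- rbind(dat, transform(dat, subject_id = subject_id + 1000))
  expect_equal(pooled_loglik(dat2, p, spec1), 2 * l1)

  # brute-force product over 5 one-visit subjects
  d5 <- do.call(rbind, lapply(1:5, function(i) {
    make_subject(i - 1, id = i)
  }))
  expect_equal(pooled_loglik(d5, p, spec1),
               sum(stats::dpois(0:4, 0.9, log = TRUE)))

  # ZIP at p0 -> 0 nests the Poisson model
  spec2 <- model_spec("M2", "gd")
  p2 <- c(p, list(p0_intercept = stats::qlogis(1e-10), gamma = 0))
  expect_equal(pooled_loglik(dat, p2, spec2), l1, tolerance = 1e-6)
})

test_that("Laplace marginal agrees with quadrature and its limits", {
  subs <- random_subjects(50, seed = 3)
  err <- vapply(subs, function(s) {
    lap <- laplace_subject_marginal(s, gd_truth, gd5, "high")
    qd <- quadrature_subject_marginal(s, gd_truth, gd5, "high")
    abs(lap - qd) / abs(qd)
  }, numeric(1))
  # genuine Laplace error at these parameter values is ~1e-3..1e-2
  expect_lt(max(err), 2e-2)

  # error shrinks as subject information grows
  rich <- make_subject(rep(c(3, 5, 4, 6), 8), arm = "placebo")
  lap_r <- laplace_subject_marginal(rich, gd_truth, gd5, "high")
  qd_r <- quadrature_subject_marginal(rich, gd_truth, gd5, "high",
                                      nodes = 1001, width = 8)
  expect_lt(abs(lap_r - qd_r) / abs(qd_r), 2e-4)

  # degenerate random effect: marginal equals conditional at the median
  p0 <- gd_truth; p0$sigma2 <- 0
  s <- make_subject(c(0, 2))
  expect_equal(as.numeric(laplace_subject_marginal(s, p0, gd5, "high")),
               subject_conditional_loglik(s, p0$R * p0$mu1, p0, gd5, "high"))

  # Laplace does not overshoot the quadrature oracle on flat all-zero data
  flat <- make_subject(rep(0, 4))
  lap_f <- laplace_subject_marginal(flat, gd_truth, gd5, "high")
  qd_f <- quadrature_subject_marginal(flat, gd_truth, gd5, "high")
  expect_lt(as.numeric(lap_f), qd_f + 0.02)
})

test_that("mixture marginal is the two-term log-sum-exp", {
  s <- make_subject(c(0, 2), auc = 20, t = c(168, 336), arm = "q2w")
  mix <- mixture_subject_loglik(s, gd_truth, gd5)

  # compositional identity against the package's own components
  ll_low <- subject_conditional_loglik(s, gd_truth$mu1, gd_truth, gd5, "low")
  ll_high <- as.numeric(laplace_subject_marginal(s, gd_truth, gd5, "high"))
  expect_equal(mix, log(gd_truth$theta * exp(ll_low) +
                          (1 - gd_truth$theta) * exp(ll_high)),
               tolerance = 1e-12)

  # against fully independent quadrature for both terms
  qd_high <- quadrature_subject_marginal(s, gd_truth, gd5, "high")
  mix_qd <- log(gd_truth$theta * exp(ll_low) +
                  (1 - gd_truth$theta) * exp(qd_high))
  expect_equal(mix, mix_qd, tolerance = 2e-2)

  # theta -> 1 collapses to the low-activity conditional
  p1 <- gd_truth; p1$theta <- 1 - 1e-12
  expect_equal(mixture_subject_loglik(s, p1, gd5), ll_low,
               tolerance = 1e-8)

  # theta -> 0 collapses to the high-activity Laplace marginal
  p0 <- gd_truth; p0$theta <- 1e-12
  expect_equal(mixture_subject_loglik(s, p0, gd5), ll_high,
               tolerance = 1e-8)
})

test_that("nesting equalities across the model ladder", {
  dat <- small_cohort(60, seed = 21)
  # M4 with omega2 = 0 equals pooled NB at the same parameters (onset kept)
  spec4 <- model_spec("M4", "gd")
  spec3on <- model_spec("M3", "gd", onset = TRUE)
  p4 <- list(mu = 0.7, beta = -0.02, t_half = 90, ovdp = 1.1, omega2 = 0)
  p3 <- list(lam0 = 0.7, beta = -0.02, t_half = 90, ovdp = 1.1)
  expect_equal(sum(marginal_loglik(dat, p4, spec4)),
               sum(marginal_loglik(dat, p3, spec3on)), tolerance = 1e-8)

  # M2 at p0 = 0 equals M1 on the same data
  spec1 <- model_spec("M1", "gd"); spec2 <- model_spec("M2", "gd")
  p1 <- list(lam0 = 0.8, beta = -0.015, t_half = 100)
  p2 <- c(p1, list(p0_intercept = stats::qlogis(1e-11), gamma = 0))
  expect_equal(sum(marginal_loglik(dat, p2, spec2)),
               sum(marginal_loglik(dat, p1, spec1)), tolerance = 1e-6)
})

test_that("OFV bookkeeping: -2 log-likelihood, order invariance", {
  dat <- small_cohort(40, seed = 22)
  ll <- sum(marginal_loglik(dat, gd_truth, gd5))
  expect_equal(total_ofv(dat, gd_truth, gd5), -2 * ll)

  # invariant to subject ordering
  perm <- dat[order(-dat$subject_id, dat$visit_day), ]
  expect_equal(total_ofv(perm, gd_truth, gd5),
               total_ofv(dat, gd_truth, gd5), tolerance = 1e-10)

  # invariant to an unconstrained round trip of the parameters
  u <- to_unconstrained(gd_truth, gd5)
  back <- from_unconstrained(u, gd5)
  expect_equal(unlist(back), unlist(gd_truth[gd5$params]),
               tolerance = 1e-12)
  expect_equal(total_ofv(dat, back, gd5), total_ofv(dat, gd_truth, gd5),
               tolerance = 1e-10)
})
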