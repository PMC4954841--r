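# Structural (deterministic) model components: steady-state exposure,
# exposure effect on the distribution mean, first-order effect onset, and the
# two-subpopulation mixture on baseline lesion activity.

#' Steady-state exposure from dose regimen and clearance
#'
#' `AUCss = DOSE * N / CL`, where `N` is the number of administrations per
#' 4 weeks (2 for every-2-week, 1 for every-4-week dosing, 0 for placebo) and
#' `CL` the individual post-hoc clearance. With dose in mcg and clearance in
#' L/h the result is in ng·h/mL.
#'
#' @param cl Clearance (L/h, > 0); may be a vector.
#' @param n_doses Doses per 4 weeks: 0 (placebo), 1 or 2.
#' @param dose Dose per administration in mcg (default 125).
#' @return AUCss in ng·h/mL; 0 for placebo.
#' @examples
#' compute_auc_ss(cl = 10, n_doses = 2) # 25
#' @export
compute_auc_ss <- function(cl, n_doses, dose = 125) {
  if (!all(n_doses %in% c(0, 1, 2))) stop("'n_doses' must be 0, 1 or 2")
  active <- n_doses > 0
  if (any(active & (!is.finite(cl) | cl <= 0))) {
    stop("'cl' must be > 0 for treated subjects")
  }
  out <- numeric(length(cl) * 0 + max(length(cl), length(n_doses)))
  cl <- rep_len(cl, length(out)); n_doses <- rep_len(n_doses, length(out))
  out[n_doses > 0] <- dose * n_doses[n_doses > 0] / cl[n_doses > 0]
  out
}

#' First-order effect-onset multiplier
#'
#' `1 - exp(-c * t / t_half)` with `c = log(2)` by default, so the exposure
#' effect reaches exactly half its steady-state magnitude at `t = t_half`.
#' `t = 0` (baseline, or any placebo visit) gives 0, i.e. no drug effect.
#'
#' @param t Days since the first active dose (>= 0).
#' @param t_half Onset half-life in days (> 0).
#' @param rate_const Numerator of the rate constant; `log(2)` by default,
#'   set to `0.69` to reproduce the truncated literature constant.
#' @return Multiplier in `[0, 1)`.
#' @export
onset_multiplier <- function(t, t_half, rate_const = log(2)) {
  if (any(t < 0)) stop("'t' must be >= 0")
  if (t_half <= 0) stop("'t_half' must be > 0")
  -expm1(-rate_const * t / t_half)
}

#' Proportional exposure effect on the distribution mean
#'
#' Log-linear form: `exp(beta * auc * onset)`. Emax form:
#' `1 - emax * onset * auc / (ec50 + auc)`. Both return 1 at `auc = 0`.
#' The onset factor scales the exposure term itself (inside the exponent for
#' the log-linear form, inside the bracket for the Emax form).
#'
#' @param auc Steady-state exposure (ng·h/mL, >= 0).
#' @param form `"loglinear"` or `"emax"`.
#' @param beta Slope of the AUCss effect on `log(lambda)` (log-linear form).
#' @param emax Maximal proportional reduction in `[0, 1]` (Emax form).
#' @param ec50 AUCss giving half the maximal reduction (> 0, Emax form).
#' @param onset Onset multiplier in `[0, 1]`, see [onset_multiplier()];
#'   default 1 (steady-state effect).
#' @return Multiplicative factor on the baseline mean.
#' @export
exposure_multiplier <- function(auc, form = c("loglinear", "emax"),
                                beta = NULL, emax = NULL, ec50 = NULL,
                                onset = 1) {
  form <- match.arg(form)
  if (any(auc < 0)) stop("'auc' must be >= 0")
  if (form == "loglinear") {
    if (is.null(beta)) stop("log-linear form requires 'beta'")
    exp(beta * auc * onset)
  } else {
    if (is.null(emax) || is.null(ec50)) stop("Emax form requires 'emax' and 'ec50'")
    if (ec50 <= 0) stop("'ec50' must be > 0")
    1 - emax * onset * auc / (ec50 + auc)
  }
}

#' Zero-inflation probability at a given exposure
#'
#' Inverse logit of `p0_intercept + gamma * auc`: the inflated zero
#' proportion of a zero-inflated model as a logistic function of exposure.
#'
#' @inheritParams exposure_multiplier
#' @param p0_intercept Logit-scale intercept (the value at `auc = 0` is
#'   `plogis(p0_intercept)`).
#' @param gamma Logit-scale slope of the AUCss effect.
#' @export
p0_at_exposure <- function(auc, p0_intercept, gamma = 0) {
  if (any(auc < 0)) stop("'auc' must be >= 0")
  stats::plogis(p0_intercept + gamma * auc)
}

#' Per-visit distribution means along a subject's trajectory
#'
#' For Gd+ counts the mean at visit `j` is
#' `lambda0 * exp(beta * auc_j * onset(t_j))`; on placebo (`auc = 0`) the
#' mean stays at `lambda0`. For interval-based T2 counts the onset term is
#' dropped and the mean is proportional to the observation-interval length:
#' `lambda0 * interval_days * exp(beta * auc_j)` with `lambda0` in lesions
#' per day.
#'
#' @param lambda0 Baseline mean (> 0): lesions/visit (Gd+) or lesions/day (T2).
#' @param auc,t Vectors of per-visit AUCss and days since first active dose.
#' @param params List with the exposure-effect (and for Gd+ the onset)
#'   parameters: `beta` (or `emax`/`ec50`), optionally `t_half`.
#' @param endpoint `"gd"` (per-visit counts, onset applies) or `"t2"`
#'   (interval counts, duration-proportional, no onset).
#' @param interval_days Per-visit interval lengths (required for `"t2"`).
#' @param form Exposure-effect form passed to [exposure_multiplier()].
#' @return Vector of per-visit means `lambda_ij`.
#' @export
lambda_trajectory <- function(lambda0, auc, t, params,
                              endpoint = c("gd", "t2"),
                              interval_days = NULL,
                              form = c("loglinear", "emax")) {
  endpoint <- match.arg(endpoint); form <- match.arg(form)
  if (any(lambda0 <= 0)) stop("'lambda0' must be > 0")
  ons <- if (endpoint == "gd") {
    if (is.null(params$t_half)) 1 else onset_multiplier(t, params$t_half)
  } else 1
  mult <- exposure_multiplier(auc, form = form, beta = params$beta,
                              emax = params$emax, ec50 = params$ec50,
                              onset = ons)
  lam <- lambda0 * mult
  if (endpoint == "t2") {
    if (is.null(interval_days) || any(interval_days <= 0)) {
      stop("'t2' endpoint requires positive 'interval_days'")
    }
    lam <- lam * interval_days
  }
  lam
}

#' Draw baseline activity from the two-subpopulation mixture
#'
#' A subject belongs to the low-activity subpopulation (`Y = 1`) with
#' probability `theta`; its baseline mean is lognormal with median `mu1` and
#' log-variance `omega2_low` (a point mass at `mu1` when 0, the default).
#' Otherwise the baseline mean is lognormal with median `mu2 = R * mu1` and
#' log-variance `sigma2`.
#'
#' @param n Number of subjects.
#' @param mix List with `mu1`, `R`, `theta`, `sigma2` and optionally
#'   `omega2_low` (default 0), e.g. [final_params()].
#' @return `data.frame` with columns `Y` (1 = low activity) and `lambda0`.
#' @export
draw_baseline_mixture <- function(n, mix) {
  stopifnot(mix$mu1 > 0, mix$R > 0, mix$theta > 0, mix$theta < 1,
            mix$sigma2 >= 0)
  omega2_low <- if (is.null(mix$omega2_low)) 0 else mix$omega2_low
  y <- stats::rbinom(n, 1L, mix$theta)
  lambda0 <- numeric(n)
  low <- y == 1L
  lambda0[low] <- mix$mu1 * exp(stats::rnorm(sum(low), 0, sqrt(omega2_low)))
  lambda0[!low] <- mix$R * mix$mu1 *
    exp(stats::rnorm(sum(!low), 0, sqrt(mix$sigma2)))
  data.frame(Y = y, lambda0 = lambda0)
}

#' Typical-subject weighted mean baseline activity
#'
#' `theta * mu1 + (1 - theta) * mu2`, the population-weighted mean of the two
#' subpopulation medians (typical-value weighting, not lognormal-mean
#' weighting).
#'
#' @inheritParams draw_baseline_mixture
#' @export
population_mean_baseline <- function(mix) {
  mix$theta * mix$mu1 + (1 - mix$theta) * mix$R * mix$mu1
}

#' Coefficient of variation implied by a lognormal log-variance
#'
#' The first-order convention `100 * sqrt(var)` (percent) used to report
#' between-subject variability of lognormal random effects.
#'
#' @param var Log-scale variance (>= 0).
#' @export
cv_from_log_variance <- function(var) {
  if (any(var < 0)) stop("'var' must be >= 0")
  100 * sqrt(var)
}

#' Published final-model parameter values
#'
#' Point estimates of the final mixture negative binomial model from the
#' ADVANCE peginterferon beta-1a exposure-response analysis, usable as
#' simulation truth: `mu1` (baseline mean, lesions/visit for Gd+ and
#' lesions/day for T2, low-activity subpopulation), `R = mu2/mu1`, `theta`
#' (low-activity proportion), `ovdp_low`/`ovdp_high` (per-subpopulation NB
#' over-dispersion), `beta` (AUCss slope on log lambda), `sigma2`
#' (log-variance of baseline in the high-activity subpopulation), and for
#' Gd+ the onset half-life `t_half` (days).
#'
#' @param endpoint `"gd"` or `"t2"`.
#' @return Named list of natural-scale parameter values.
#' @export
final_params <- function(endpoint = c("gd", "t2")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "gd") {
    list(mu1 = 0.48, R = 3.53, theta = 0.602,
         ovdp_low = 44.8, ovdp_high = 0.499,
         beta = -0.0256, t_half = 115, sigma2 = 1.25, omega2_low = 0)
  } else {
    list(mu1 = 0.0066, R = 4.71, theta = 0.354,
         ovdp_low = 35.7, ovdp_high = 0.459,
         beta = -0.0147, sigma2 = 1.21, omega2_low = 0)
  }
}

#' Bootstrap 95% confidence intervals for the final-model parameters
#'
#' Reported nonparametric-bootstrap percentile intervals matching
#' [final_params()]; used for parameter-recovery checks.
#'
#' @inheritParams final_params
#' @return Named list of length-2 numeric vectors `(lower, upper)`.
#' @export
final_params_ci <- function(endpoint = c("gd", "t2")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "gd") {
    list(mu1 = c(0.382, 0.609), R = c(2.58, 4.73),
         ovdp_low = c(39.6, 50.8), ovdp_high = c(0.398, 0.586),
         theta = c(0.561, 0.651), beta = c(-0.0304, -0.0216),
         t_half = c(73.8, 179.6), sigma2 = c(1.00, 1.46))
  } else {
    list(mu1 = c(0.0049, 0.0089), R = c(3.48, 6.25),
         ovdp_low = c(30.6, 40.6), ovdp_high = c(0.396, 0.518),
         theta = c(0.315, 0.394), beta = c(-0.0170, -0.0124),
         sigma2 = c(1.05, 1.39))
  }
}
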