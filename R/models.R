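# Model ladder and parameter handling.
#
# M1  naive pooled Poisson
# M2  naive pooled zero-inflated Poisson, logistic AUC effect on P0
# M3  naive pooled negative binomial
# M4  mixed-effects NB, lognormal random effect on baseline lambda
# M5  two-subpopulation mixture NB, subpopulation-specific over-dispersion
#
# Estimation is carried out on unconstrained transforms (log for positive
# parameters, logit for probabilities, identity for slopes).

.PARAM_TRANSFORM <- c(
  lam0 = "log", mu = "log", mu1 = "log", R = "log",
  ovdp = "log", ovdp_low = "log", ovdp_high = "log",
  t_half = "log", omega2 = "log", sigma2 = "log",
  theta = "logit", emax = "logit",
  ec50 = "log",
  beta = "identity", gamma = "identity", p0_intercept = "identity")

#' Specify one of the five candidate count models
#'
#' @param model `"M1"` ... `"M5"` (pooled Poisson, pooled ZIP, pooled NB,
#'   mixed-effects NB, mixture NB).
#' @param endpoint `"gd"` (per-visit counts with first-order effect onset)
#'   or `"t2"` (interval counts, means proportional to interval length,
#'   no onset).
#' @param effect_form `"loglinear"` (slope `beta` on `log(lambda)`) or
#'   `"emax"` (`emax`, `ec50`).
#' @param onset Logical; whether the first-order onset half-life is
#'   estimated. Defaults to `TRUE` for Gd+ except M3 (where the time effect
#'   is removed to allow convergence) and `FALSE` for T2.
#' @return A list of class `"lesionmix_spec"` with the model flags and the
#'   names of its estimable parameters.
#' @export
model_spec <- function(model = c("M5", "M1", "M2", "M3", "M4"),
                       endpoint = c("gd", "t2"),
                       effect_form = c("loglinear", "emax"),
                       onset = NULL) {
  model <- match.arg(model)
  endpoint <- match.arg(endpoint)
  effect_form <- match.arg(effect_form)
  if (is.null(onset)) onset <- endpoint == "gd" && model != "M3"
  if (endpoint == "t2" && onset) stop("onset is not used for the T2 endpoint")
  eff <- if (effect_form == "loglinear") "beta" else c("emax", "ec50")
  ons <- if (onset) "t_half" else character()
  pars <- switch(model,
    M1 = c("lam0", eff, ons),
    M2 = c("lam0", eff, ons, "p0_intercept", "gamma"),
    M3 = c("lam0", eff, ons, "ovdp"),
    M4 = c("mu", eff, ons, "ovdp", "omega2"),
    M5 = c("mu1", "R", "theta", "ovdp_low", "ovdp_high", eff, ons, "sigma2"))
  structure(list(model = model, endpoint = endpoint,
                 effect_form = effect_form, onset = onset,
                 mixed = model == "M4", mixture = model == "M5",
                 p0_effect = model == "M2", params = pars),
            class = "lesionmix_spec")
}

#' @export
print.lesionmix_spec <- function(x, ...) {
  cat(sprintf("Count model %s (%s endpoint, %s exposure effect%s)\n",
              x$model, x$endpoint, x$effect_form,
              if (x$onset) ", first-order onset" else ""))
  cat("Parameters:", paste(x$params, collapse = ", "), "\n")
  invisible(x)
}

# natural-scale named list -> unconstrained named vector, and back
to_unconstrained <- function(params, spec) {
  vapply(spec$params, function(nm) {
    v <- params[[nm]]
    if (is.null(v)) stop("missing parameter '", nm, "'")
    switch(.PARAM_TRANSFORM[[nm]],
           log = log(v), logit = stats::qlogis(v), identity = v)
  }, numeric(1))
}

from_unconstrained <- function(u, spec) {
  u <- unname(u)
  out <- lapply(seq_along(spec$params), function(i) {
    nm <- spec$params[i]
    switch(.PARAM_TRANSFORM[[nm]],
           log = exp(u[i]), logit = stats::plogis(u[i]), identity = u[i])
  })
  names(out) <- spec$params
  out
}

# derivative of the natural parameter w.r.t. its unconstrained transform
.dnatural_du <- function(params, spec) {
  vapply(spec$params, function(nm) {
    v <- params[[nm]]
    switch(.PARAM_TRANSFORM[[nm]],
           log = v, logit = v * (1 - v), identity = 1)
  }, numeric(1))
}

#' Moment-based starting values for a model fit
#'
#' Data-driven heuristics: the placebo/baseline rows (`auc_ss == 0`) give
#' the baseline mean (per day for T2), the observed mean-variance gap gives
#' the pooled over-dispersion, and the fraction of subjects with no lesions
#' at any visit initializes the low-activity mixture proportion.
#'
#' @param dataset Long-format dataset, see [simulate_trial()].
#' @param spec A [model_spec()].
#' @return Named list of natural-scale starting values.
#' @export
default_inits <- function(dataset, spec) {
  validate_dataset(dataset)
  y <- dataset$count
  rate <- if (spec$endpoint == "t2") y / dataset$interval_days else y
  base_rows <- dataset$auc_ss == 0
  m0 <- max(mean(rate[base_rows]), 1e-3)
  v0 <- stats::var(y[base_rows])
  ovdp0 <- max((v0 - mean(y[base_rows])) / mean(y[base_rows])^2, 0.5)
  allzero <- tapply(y, dataset$subject_id, function(z) all(z == 0))
  th0 <- min(max(mean(allzero), 0.15), 0.85)
  init <- list(lam0 = m0, mu = 0.6 * m0,
               mu1 = 0.5 * m0, R = 3, theta = th0,
               ovdp = ovdp0, ovdp_low = min(ovdp0, 20), ovdp_high = 1,
               beta = -0.01, emax = 0.5, ec50 = 15,
               t_half = 60, p0_intercept = 0, gamma = 0.01,
               omega2 = 1, sigma2 = 1)
  init[spec$params]
}
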