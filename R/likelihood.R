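# Marginal, mixed-effects and mixture log-likelihoods.
#
# Random effects enter as one scalar eta per subject on log(lambda_i0); the
# marginal over eta is computed by a 1-D Laplace approximation whose inner
# mode search is a damped Newton iteration run simultaneously for all
# subjects (the per-subject log-posterior in eta is strictly concave for the
# Poisson and NB families, so Newton from eta = 0 is safe). A trapezoid
# quadrature over eta is provided as an independent oracle for testing.

# ---- internal row-level machinery ------------------------------------------

.lp_rows <- function(k, lam, ovdp) {
  if (ovdp < .OVDP_POISSON_LIMIT) stats::dpois(k, lam, log = TRUE)
  else stats::dnbinom(k, size = 1 / ovdp, mu = lam, log = TRUE)
}

# d/d(log lambda) and d2/d(log lambda)^2 of the row log-pmf
.grad_rows <- function(k, lam, ovdp) {
  if (ovdp < .OVDP_POISSON_LIMIT) k - lam
  else { a <- 1 / ovdp; k - lam * (k + a) / (a + lam) }
}

.hess_rows <- function(k, lam, ovdp) {
  if (ovdp < .OVDP_POISSON_LIMIT) -lam
  else { a <- 1 / ovdp; -(k + a) * a * lam / (a + lam)^2 }
}

.by_subject <- function(x, si, n_s) {
  tmp <- rowsum(x, si)
  out <- numeric(n_s)
  out[as.integer(rownames(tmp))] <- tmp[, 1]
  out
}

.prep_data <- function(dataset, spec) {
  validate_dataset(dataset)
  if (spec$endpoint == "t2" && anyNA(dataset$interval_days)) {
    stop("T2 models require 'interval_days' on every row")
  }
  ids <- unique(dataset$subject_id)
  list(k = as.integer(dataset$count),
       auc = dataset$auc_ss,
       t = dataset$t_active_days,
       interval = dataset$interval_days,
       si = match(dataset$subject_id, ids),
       ids = ids, n_s = length(ids))
}

# per-row multiplicative factor on the baseline mean
.row_multiplier <- function(pd, params, spec) {
  ons <- if (spec$onset) onset_multiplier(pd$t, params$t_half) else 1
  m <- exposure_multiplier(pd$auc, form = spec$effect_form,
                           beta = params$beta, emax = params$emax,
                           ec50 = params$ec50, onset = ons)
  if (spec$endpoint == "t2") m <- m * pd$interval
  m
}

# Laplace marginal log-likelihood per subject for lambda_i0 = mu * exp(eta),
# eta ~ N(0, sigma2). base_lam holds the per-row means at eta = 0.
.laplace_engine <- function(k, base_lam, si, n_s, ovdp, sigma2,
                            tol = 1e-9, max_iter = 100) {
  if (sigma2 < 1e-10) {
    ll <- .by_subject(.lp_rows(k, base_lam, ovdp), si, n_s)
    return(list(ll = ll, eta = numeric(n_s),
                neg_hess = rep(Inf, n_s), iter = 0L))
  }
  eta <- numeric(n_s)
  h <- rep(-1 / sigma2, n_s)
  for (it in seq_len(max_iter)) {
    lam <- base_lam * exp(eta[si])
    g <- .by_subject(.grad_rows(k, lam, ovdp), si, n_s) - eta / sigma2
    h <- .by_subject(.hess_rows(k, lam, ovdp), si, n_s) - 1 / sigma2
    step <- g / h
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -3), 3)
    eta <- eta - step
    if (max(abs(g)) < tol) break
  }
  lam <- base_lam * exp(eta[si])
  h <- .by_subject(.hess_rows(k, lam, ovdp), si, n_s) - 1 / sigma2
  ll <- .by_subject(.lp_rows(k, lam, ovdp), si, n_s) +
    stats::dnorm(eta, 0, sqrt(sigma2), log = TRUE) +
    0.5 * log(2 * pi) - 0.5 * log(-h)
  list(ll = ll, eta = eta, neg_hess = -h, iter = it)
}

# per-subject marginal log-likelihood vector for any model
.subject_loglik <- function(pd, params, spec) {
  m <- .row_multiplier(pd, params, spec)
  if (any(!is.finite(m)) || any(m <= 0)) stop("non-finite per-visit mean")
  if (spec$model %in% c("M1", "M2", "M3")) {
    lam <- params$lam0 * m
    lp <- switch(spec$model,
      M1 = stats::dpois(pd$k, lam, log = TRUE),
      M2 = {
        p0 <- pmin(stats::plogis(params$p0_intercept + params$gamma * pd$auc),
                   1 - 1e-12)
        zip_logpmf(pd$k, lam, p0)
      },
      M3 = .lp_rows(pd$k, lam, params$ovdp))
    .by_subject(lp, pd$si, pd$n_s)
  } else if (spec$model == "M4") {
    .laplace_engine(pd$k, params$mu * m, pd$si, pd$n_s,
                    params$ovdp, params$omega2)$ll
  } else {
    o2l <- if (is.null(params$omega2_low)) 0 else params$omega2_low
    ll_low <- if (o2l > 0) {
      .laplace_engine(pd$k, params$mu1 * m, pd$si, pd$n_s,
                      params$ovdp_low, o2l)$ll
    } else {
      .by_subject(.lp_rows(pd$k, params$mu1 * m, params$ovdp_low),
                  pd$si, pd$n_s)
    }
    ll_high <- .laplace_engine(pd$k, params$R * params$mu1 * m,
                               pd$si, pd$n_s,
                               params$ovdp_high, params$sigma2)$ll
    .logspace_add(log(params$theta) + ll_low,
                  log1p(-params$theta) + ll_high)
  }
}

# ---- exported likelihood surface -------------------------------------------

#' Per-subject marginal log-likelihood
#'
#' For the pooled models this is the conditional log-likelihood summed over
#' a subject's visits; for M4 the Laplace-approximated marginal over the
#' baseline random effect; for M5 the two-term mixture
#' `theta * L_low + (1 - theta) * L_high` (log-sum-exp), with the
#' low-activity term evaluated in closed form at `lambda_i0 = mu1` and the
#' high-activity term by Laplace with median `R * mu1` and log-variance
#' `sigma2`.
#'
#' @param dataset Long-format dataset, see [simulate_trial()].
#' @param params Named list of natural-scale parameters for `spec`.
#' @param spec A [model_spec()].
#' @return Numeric vector, one log-likelihood per subject (in order of first
#'   appearance), with subject ids as names.
#' @export
marginal_loglik <- function(dataset, params, spec) {
  pd <- .prep_data(dataset, spec)
  out <- .subject_loglik(pd, params, spec)
  names(out) <- pd$ids
  out
}

#' Objective function value (-2 log-likelihood)
#'
#' The model-comparison statistic: `-2` times the total marginal
#' log-likelihood over subjects. Non-finite subject contributions raise an
#' error naming the offending subjects.
#'
#' @inheritParams marginal_loglik
#' @export
total_ofv <- function(dataset, params, spec) {
  ll <- marginal_loglik(dataset, params, spec)
  if (any(!is.finite(ll))) {
    stop("non-finite log-likelihood for subject(s): ",
         paste(utils::head(names(ll)[!is.finite(ll)], 5), collapse = ", "))
  }
  -2 * sum(ll)
}

#' Conditional log-likelihood of one subject at a known baseline mean
#'
#' Sum over the subject's visits of the count log-pmf at
#' `lambda_ij = lambda0 * multiplier(auc_ij, t_ij)`, conditional on
#' `lambda0`. Dispersion / zero-inflation parameters are taken from
#' `params` according to `spec` (for M5, `subpop` selects which
#' over-dispersion applies).
#'
#' @param subject Rows of one subject (long-format schema).
#' @param lambda0 Baseline mean for this subject (> 0).
#' @param params,spec As in [marginal_loglik()].
#' @param subpop `"low"` or `"high"` (mixture models only).
#' @export
subject_conditional_loglik <- function(subject, lambda0, params, spec,
                                       subpop = c("high", "low")) {
  subpop <- match.arg(subpop)
  pd <- .prep_data(subject, spec)
  if (pd$n_s != 1L) stop("'subject' must contain a single subject")
  m <- .row_multiplier(pd, params, spec)
  lam <- lambda0 * m
  lp <- switch(spec$model,
    M1 = stats::dpois(pd$k, lam, log = TRUE),
    M2 = zip_logpmf(pd$k, lam,
                    pmin(stats::plogis(params$p0_intercept +
                                         params$gamma * pd$auc), 1 - 1e-12)),
    M3 = .lp_rows(pd$k, lam, params$ovdp),
    M4 = .lp_rows(pd$k, lam, params$ovdp),
    M5 = .lp_rows(pd$k, lam,
                  if (subpop == "low") params$ovdp_low else params$ovdp_high))
  sum(lp)
}

#' Pooled-model total log-likelihood
#'
#' All subjects share the baseline mean `lam0` (models M1-M3); the total is
#' the sum of the per-subject conditional log-likelihoods.
#'
#' @inheritParams marginal_loglik
#' @export
pooled_loglik <- function(dataset, params, spec) {
  if (!spec$model %in% c("M1", "M2", "M3")) {
    stop("pooled_loglik() applies to models M1-M3")
  }
  sum(marginal_loglik(dataset, params, spec))
}

#' Laplace marginal log-likelihood of one subject
#'
#' Integrates the subject's conditional likelihood over the lognormal
#' baseline random effect by a 1-D Laplace approximation: the mode of
#' `h(eta) = conditional loglik + log N(eta; 0, sigma2)` is found by
#' safeguarded Newton and the marginal is
#' `h(eta_hat) + log(2*pi)/2 - log(-h''(eta_hat))/2`. With `sigma2 = 0` the
#' conditional log-likelihood at `eta = 0` is returned.
#'
#' @inheritParams subject_conditional_loglik
#' @param subpop For M5, which subpopulation's median/dispersion to use
#'   (`"high"`: median `R*mu1`, dispersion `ovdp_high`, variance `sigma2`).
#'   For M4 the single population (`mu`, `ovdp`, `omega2`) is used.
#' @return Scalar log marginal likelihood, with the mode `eta_hat` and the
#'   negative curvature as attributes.
#' @export
laplace_subject_marginal <- function(subject, params, spec,
                                     subpop = c("high", "low")) {
  subpop <- match.arg(subpop)
  pd <- .prep_data(subject, spec)
  if (pd$n_s != 1L) stop("'subject' must contain a single subject")
  m <- .row_multiplier(pd, params, spec)
  cfg <- .subpop_config(params, spec, subpop)
  res <- .laplace_engine(pd$k, cfg$mu * m, pd$si, 1L, cfg$ovdp, cfg$sigma2)
  structure(res$ll, eta_hat = res$eta, neg_hess = res$neg_hess)
}

.subpop_config <- function(params, spec, subpop) {
  if (spec$model == "M4") {
    list(mu = params$mu, ovdp = params$ovdp, sigma2 = params$omega2)
  } else if (spec$model == "M5") {
    if (subpop == "high") {
      list(mu = params$R * params$mu1, ovdp = params$ovdp_high,
           sigma2 = params$sigma2)
    } else {
      o2l <- if (is.null(params$omega2_low)) 0 else params$omega2_low
      list(mu = params$mu1, ovdp = params$ovdp_low, sigma2 = o2l)
    }
  } else stop("random effects apply to models M4/M5 only")
}

#' Trapezoid-quadrature marginal log-likelihood of one subject
#'
#' Brute-force oracle for [laplace_subject_marginal()]: trapezoid
#' integration of the joint density over an equally spaced eta grid spanning
#' `width` prior standard deviations.
#'
#' @inheritParams laplace_subject_marginal
#' @param nodes Number of grid nodes (default 201).
#' @param width Half-width of the grid in prior SDs (default 6).
#' @export
quadrature_subject_marginal <- function(subject, params, spec,
                                        subpop = c("high", "low"),
                                        nodes = 201, width = 6) {
  subpop <- match.arg(subpop)
  pd <- .prep_data(subject, spec)
  if (pd$n_s != 1L) stop("'subject' must contain a single subject")
  m <- .row_multiplier(pd, params, spec)
  cfg <- .subpop_config(params, spec, subpop)
  if (cfg$sigma2 < 1e-10) return(sum(.lp_rows(pd$k, cfg$mu * m, cfg$ovdp)))
  sd <- sqrt(cfg$sigma2)
  eta <- seq(-width * sd, width * sd, length.out = nodes)
  lw <- log(c(0.5, rep(1, nodes - 2), 0.5) * diff(eta)[1])
  lj <- vapply(eta, function(e) {
    sum(.lp_rows(pd$k, cfg$mu * exp(e) * m, cfg$ovdp)) +
      stats::dnorm(e, 0, sd, log = TRUE)
  }, numeric(1))
  v <- lj + lw
  mx <- max(v)
  mx + log(sum(exp(v - mx)))
}

#' Mixture marginal log-likelihood of one subject
#'
#' `log(theta * L_low + (1 - theta) * L_high)` computed by log-sum-exp, with
#' the low-activity likelihood in closed form at `lambda_i0 = mu1` (its
#' between-subject variance is fixed to zero in the final model) and the
#' high-activity likelihood by Laplace.
#'
#' @inheritParams laplace_subject_marginal
#' @export
mixture_subject_loglik <- function(subject, params, spec) {
  if (spec$model != "M5") stop("mixture likelihood applies to model M5")
  pd <- .prep_data(subject, spec)
  if (pd$n_s != 1L) stop("'subject' must contain a single subject")
  as.numeric(.subject_loglik(pd, params, spec))
}
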