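# Maximum-likelihood fitting, uncertainty, and empirical Bayes quantities.

#' Fit a count model by (Laplace) maximum likelihood
#'
#' Maximizes the total marginal log-likelihood over the unconstrained
#' parameter transforms by quasi-Newton (BFGS), optionally with jittered
#' multi-start. Standard errors come from the inverse of the central
#' finite-difference Hessian of OFV/2 at the optimum, mapped to the natural
#' scale by the delta method.
#'
#' @param dataset Long-format dataset, see [simulate_trial()].
#' @param spec A [model_spec()].
#' @param init Named list of natural-scale starting values; defaults to
#'   [default_inits()].
#' @param n_restarts Number of additional starts from jittered initials
#'   (default 0); the best optimum is kept.
#' @param seed Seed for the restart jitter.
#' @param compute_se Compute the Hessian-based covariance (default TRUE).
#' @param control Passed to [stats::optim()] (defaults: `maxit = 1000`,
#'   `reltol = 1e-10`).
#' @return An object of class `"lesionmix_fit"`: natural-scale `estimates`,
#'   `ofv`, `se`/`rse` (natural scale, percent), unconstrained covariance,
#'   `convergence` flag, optimizer counts, and the model `spec`.
#' @export
fit_model <- function(dataset, spec, init = NULL, n_restarts = 0,
                      seed = NULL, compute_se = TRUE, control = list()) {
  pd <- .prep_data(dataset, spec)
  if (is.null(init)) init <- default_inits(dataset, spec)
  u0 <- to_unconstrained(init, spec)

  obj <- function(u) {
    v <- tryCatch(suppressWarnings({
      p <- from_unconstrained(u, spec)
      ll <- .subject_loglik(pd, p, spec)
      -2 * sum(ll)
    }), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }

  ctl <- utils::modifyList(list(maxit = 1000, reltol = 1e-10), control)
  run_one <- function(u_start) {
    stats::optim(u_start, obj, method = "BFGS", control = ctl)
  }
  best <- run_one(u0)
  if (n_restarts > 0) {
    jitters <- withr::with_seed(if (is.null(seed)) 1L else seed, {
      lapply(seq_len(n_restarts),
             function(i) u0 + stats::rnorm(length(u0), 0, 0.4))
    })
    for (uj in jitters) {
      cand <- tryCatch(run_one(uj), error = function(e) NULL)
      if (!is.null(cand) && cand$value < best$value) best <- cand
    }
  }

  u_hat <- best$par
  est <- from_unconstrained(u_hat, spec)
  se <- rse <- stats::setNames(rep(NA_real_, length(u_hat)), spec$params)
  cov_u <- NULL
  if (compute_se) {
    H <- .fd_hessian(obj, u_hat)
    cov_u <- tryCatch(solve(H / 2), error = function(e) NULL)
    if (!is.null(cov_u) && all(is.finite(cov_u)) &&
        all(diag(cov_u) > 0)) {
      se_u <- sqrt(diag(cov_u))
      se <- abs(.dnatural_du(est, spec)) * se_u
      rse <- 100 * se / abs(unlist(est))
    } else {
      cov_u <- NULL
    }
  }

  structure(list(spec = spec, estimates = est, unconstrained = u_hat,
                 ofv = best$value, se = se, rse = rse,
                 cov_unconstrained = cov_u,
                 convergence = best$convergence == 0,
                 counts = best$counts, message = best$message,
                 n_subjects = pd$n_s, n_obs = length(pd$k)),
            class = "lesionmix_fit")
}

# central finite-difference Hessian, step 1e-4 * (1 + |x|)
.fd_hessian <- function(f, x) {
  p <- length(x)
  h <- 1e-4 * (1 + abs(x))
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' @export
print.lesionmix_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit (%s endpoint), %d subjects / %d observations\n",
              x$spec$model, x$spec$endpoint, x$n_subjects, x$n_obs))
  cat(sprintf("OFV (-2 log-likelihood): %.1f   converged: %s\n",
              x$ofv, x$convergence))
  print(parameter_table(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Machine-readable parameter table of a fit
#'
#' One row per parameter: natural-scale estimate, standard error, relative
#' standard error (percent) and the transform used during estimation.
#'
#' @param fit A [fit_model()] result.
#' @export
parameter_table <- function(fit) {
  data.frame(parameter = fit$spec$params,
             estimate = unlist(fit$estimates),
             se = unname(fit$se),
             rse_pct = unname(fit$rse),
             transform = unname(.PARAM_TRANSFORM[fit$spec$params]),
             row.names = NULL)
}

#' @export
coef.lesionmix_fit <- function(object, ...) unlist(object$estimates)

#' @export
logLik.lesionmix_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$spec$params),
            class = "logLik")
}

#' Empirical Bayes quantities per subject
#'
#' For M4, the posterior mode `eta_hat` of the baseline random effect and
#' the implied individual baseline mean. For M5, the posterior probability
#' of low-activity membership `P(Y = 1 | data)` together with the
#' conditional mode of `eta` within the high-activity subpopulation.
#'
#' @param dataset Dataset the model was fitted to.
#' @param fit A converged [fit_model()] result (M4 or M5).
#' @return `data.frame` with one row per subject.
#' @export
empirical_bayes <- function(dataset, fit) {
  spec <- fit$spec
  params <- fit$estimates
  pd <- .prep_data(dataset, spec)
  m <- .row_multiplier(pd, params, spec)
  if (spec$model == "M4") {
    lap <- .laplace_engine(pd$k, params$mu * m, pd$si, pd$n_s,
                           params$ovdp, params$omega2)
    data.frame(subject_id = pd$ids, eta_hat = lap$eta,
               lambda0_eb = params$mu * exp(lap$eta))
  } else if (spec$model == "M5") {
    ll_low <- .by_subject(.lp_rows(pd$k, params$mu1 * m, params$ovdp_low),
                          pd$si, pd$n_s)
    lap <- .laplace_engine(pd$k, params$R * params$mu1 * m, pd$si, pd$n_s,
                           params$ovdp_high, params$sigma2)
    mix <- .logspace_add(log(params$theta) + ll_low,
                         log1p(-params$theta) + lap$ll)
    data.frame(subject_id = pd$ids,
               p_low = exp(log(params$theta) + ll_low - mix),
               eta_high = lap$eta,
               lambda0_high = params$R * params$mu1 * exp(lap$eta))
  } else {
    stop("empirical Bayes quantities require a mixed (M4) or mixture (M5) fit")
  }
}
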