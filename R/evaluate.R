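# Model evaluation: marginal-probability goodness of fit, visual predictive
# checks binned by AUCss, and the nonparametric bootstrap.

#' Observed marginal probability of each count
#'
#' Empirical frequency of every unique lesion count over all subject-visits.
#'
#' @param dataset Long-format dataset.
#' @return `data.frame` with columns `count` and `prob` (sums to 1).
#' @export
observed_marginal_probs <- function(dataset) {
  validate_dataset(dataset)
  tab <- table(dataset$count)
  data.frame(count = as.integer(names(tab)),
             prob = as.numeric(tab) / sum(tab))
}

# rows x counts matrix of pmf values for lam varying by row
.pmf_matrix <- function(counts, lam, ovdp = 0, p0 = NULL) {
  sapply(counts, function(k) {
    lp <- .lp_rows(rep.int(k, length(lam)), lam, ovdp)
    if (!is.null(p0)) {
      lp <- lp + log1p(-p0)
      if (k == 0L) lp <- .logspace_add(log(p0), lp)
    }
    exp(lp)
  })
}

#' Model-predicted marginal probability of each count
#'
#' The probability of each count at every subject-visit, averaged over all
#' observations. With `type = "eb"` the per-subject empirical Bayes
#' quantities are used (the posterior membership probability and conditional
#' mode for M5, the posterior mode for M4; pooled models have no
#' between-subject variation). With `type = "population"` the random effect
#' is integrated out by trapezoid quadrature instead.
#'
#' @param dataset Dataset the model was fitted to.
#' @param fit A [fit_model()] result.
#' @param max_count Largest count to tabulate; the tail mass
#'   `P(X > max_count)` is reported as attribute `"tail"`.
#' @param type `"eb"` or `"population"`.
#' @return `data.frame` with columns `count` (0..`max_count`) and `prob`.
#' @export
predicted_marginal_probs <- function(dataset, fit, max_count = 50,
                                     type = c("eb", "population")) {
  type <- match.arg(type)
  spec <- fit$spec
  p <- fit$estimates
  pd <- .prep_data(dataset, spec)
  if (max_count < max(pd$k)) {
    warning("max_count below the observed maximum; tail mass lumped")
  }
  m <- .row_multiplier(pd, p, spec)
  counts <- 0:max_count
  pm <- switch(spec$model,
    M1 = .pmf_matrix(counts, p$lam0 * m),
    M2 = .pmf_matrix(counts, p$lam0 * m, 0,
                     pmin(stats::plogis(p$p0_intercept + p$gamma * pd$auc),
                          1 - 1e-12)),
    M3 = .pmf_matrix(counts, p$lam0 * m, p$ovdp),
    M4 = if (type == "eb") {
      eb <- empirical_bayes(dataset, fit)
      .pmf_matrix(counts, eb$lambda0_eb[pd$si] * m, p$ovdp)
    } else {
      .integrate_pmf(counts, p$mu * m, p$ovdp, p$omega2)
    },
    M5 = if (type == "eb") {
      eb <- empirical_bayes(dataset, fit)
      w <- eb$p_low[pd$si]
      w * .pmf_matrix(counts, p$mu1 * m, p$ovdp_low) +
        (1 - w) * .pmf_matrix(counts, eb$lambda0_high[pd$si] * m, p$ovdp_high)
    } else {
      p$theta * .pmf_matrix(counts, p$mu1 * m, p$ovdp_low) +
        (1 - p$theta) * .integrate_pmf(counts, p$R * p$mu1 * m,
                                       p$ovdp_high, p$sigma2)
    })
  prob <- colMeans(pm)
  structure(data.frame(count = counts, prob = prob),
            tail = max(0, 1 - sum(prob)))
}

# E_eta[pmf] over eta ~ N(0, sigma2), trapezoid on a 6-SD grid
.integrate_pmf <- function(counts, base_lam, ovdp, sigma2, nodes = 61) {
  if (sigma2 < 1e-10) return(.pmf_matrix(counts, base_lam, ovdp))
  sd <- sqrt(sigma2)
  eta <- seq(-6 * sd, 6 * sd, length.out = nodes)
  w <- stats::dnorm(eta, 0, sd) * c(0.5, rep(1, nodes - 2), 0.5) *
    diff(eta)[1]
  w <- w / sum(w)
  out <- 0
  for (i in seq_along(eta)) {
    out <- out + w[i] * .pmf_matrix(counts, base_lam * exp(eta[i]), ovdp)
  }
  out
}

# bin observations by AUCss: bin 0 for zero AUC, equal-count quantile bins
# for positive AUC; ties go to the lower bin
.auc_bins <- function(auc, n_bins = 21, min_per_bin = 5) {
  pos <- auc > 0
  k <- n_bins - 1
  repeat {
    edges <- unique(stats::quantile(auc[pos], probs = seq(0, 1, length.out = k + 1)))
    bin <- integer(length(auc))
    bin[pos] <- cut(auc[pos], breaks = edges, include.lowest = TRUE,
                    labels = FALSE)
    n_per <- table(bin[pos])
    if (all(n_per >= min_per_bin) || k <= 2) break
    k <- k - 1
    message("merging sparse AUC bins; using ", k, " positive-AUC bins")
  }
  list(bin = bin, edges = edges)
}

.categorize <- function(count, categories) {
  # categories: upper value of each singleton group; anything larger lumped
  labs <- c(as.character(categories), paste0(">", max(categories)))
  i <- match(count, categories)
  i[is.na(i)] <- length(labs)
  factor(labs[i], levels = labs)
}

# simulate one replicate of counts at the fitted model, design held fixed
.simulate_counts_at_fit <- function(pd, m, fit) {
  p <- fit$estimates
  spec <- fit$spec
  n_s <- pd$n_s
  switch(spec$model,
    M1 = rcount(length(m), p$lam0 * m, family = "poisson"),
    M2 = rcount(length(m), p$lam0 * m,
                p0 = pmin(stats::plogis(p$p0_intercept + p$gamma * pd$auc),
                          1 - 1e-12),
                family = "zip"),
    M3 = rcount(length(m), p$lam0 * m, ovdp = p$ovdp, family = "nb"),
    M4 = {
      lam0 <- p$mu * exp(stats::rnorm(n_s, 0, sqrt(p$omega2)))
      rcount(length(m), lam0[pd$si] * m, ovdp = p$ovdp, family = "nb")
    },
    M5 = {
      y <- stats::rbinom(n_s, 1L, p$theta)
      lam0 <- ifelse(y == 1L, p$mu1,
                     p$R * p$mu1 * exp(stats::rnorm(n_s, 0, sqrt(p$sigma2))))
      ovdp <- ifelse(y == 1L, p$ovdp_low, p$ovdp_high)
      rcount(length(m), lam0[pd$si] * m, ovdp = ovdp[pd$si], family = "nb")
    })
}

#' Visual predictive check binned by steady-state exposure
#'
#' Simulates `n_reps` replicate datasets at the fitted model (drawing new
#' subpopulation labels and random effects per subject while keeping every
#' subject's AUCss/visit design fixed), bins observations by AUCss (one
#' zero-AUC bin plus equal-count quantile bins), and summarizes per
#' bin-by-category observed proportions against simulation percentile
#' prediction intervals, plus per-bin mean and variance of counts.
#'
#' @param dataset Dataset the model was fitted to.
#' @param fit A converged [fit_model()] result.
#' @param n_reps Number of simulation replicates (default 500).
#' @param n_bins Total number of AUC bins including the zero bin (21).
#' @param categories Singleton count categories; larger counts are lumped
#'   into one `> max` group (default `0:7` plus `>7`).
#' @param pi_level Prediction-interval level for category proportions (0.90).
#' @param mean_pi_level Prediction-interval level for bin means/variances
#'   (0.95).
#' @param seed Optional seed for the simulation replicates.
#' @return An object of class `"lesionmix_vpc"` with elements `summary`
#'   (bin x category observed proportion and PI), `moments` (per-bin
#'   observed mean/variance with PIs), `edges`, `n_reps`, `pi_level`.
#' @export
vpc <- function(dataset, fit, n_reps = 500, n_bins = 21, categories = 0:7,
                pi_level = 0.90, mean_pi_level = 0.95, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, vpc(dataset, fit, n_reps = n_reps,
                                      n_bins = n_bins,
                                      categories = categories,
                                      pi_level = pi_level,
                                      mean_pi_level = mean_pi_level)))
  }
  spec <- fit$spec
  pd <- .prep_data(dataset, spec)
  m <- .row_multiplier(pd, fit$estimates, spec)
  bins <- .auc_bins(pd$auc, n_bins)
  bin <- factor(bins$bin, levels = sort(unique(bins$bin)))
  n_cat <- length(categories) + 1L
  prop_of <- function(counts) {
    tab <- table(bin, .categorize(counts, categories))
    sweep(unclass(tab), 1, rowSums(tab), "/")
  }
  obs_prop <- prop_of(pd$k)
  obs_mean <- tapply(pd$k, bin, mean)
  obs_var <- tapply(pd$k, bin, stats::var)

  sim_prop <- array(NA_real_, c(nlevels(bin), n_cat, n_reps))
  sim_mean <- sim_var <- matrix(NA_real_, nlevels(bin), n_reps)
  for (r in seq_len(n_reps)) {
    ks <- .simulate_counts_at_fit(pd, m, fit)
    sim_prop[, , r] <- prop_of(ks)
    sim_mean[, r] <- tapply(ks, bin, mean)
    sim_var[, r] <- tapply(ks, bin, stats::var)
  }
  a <- (1 - pi_level) / 2
  lo <- apply(sim_prop, c(1, 2), stats::quantile, probs = a, na.rm = TRUE)
  hi <- apply(sim_prop, c(1, 2), stats::quantile, probs = 1 - a, na.rm = TRUE)
  am <- (1 - mean_pi_level) / 2
  qm <- function(x, p) apply(x, 1, stats::quantile, probs = p, na.rm = TRUE)

  cat_labs <- colnames(obs_prop)
  summary <- data.frame(
    bin = rep(as.integer(levels(bin)), times = n_cat),
    category = rep(cat_labs, each = nlevels(bin)),
    observed = as.vector(obs_prop),
    pi_lo = as.vector(lo), pi_hi = as.vector(hi))
  moments <- data.frame(
    bin = as.integer(levels(bin)),
    n = as.integer(table(bin)),
    obs_mean = as.numeric(obs_mean),
    mean_lo = qm(sim_mean, am), mean_hi = qm(sim_mean, 1 - am),
    obs_var = as.numeric(obs_var),
    var_lo = qm(sim_var, am), var_hi = qm(sim_var, 1 - am))
  structure(list(summary = summary, moments = moments,
                 edges = bins$edges, n_reps = n_reps,
                 pi_level = pi_level, mean_pi_level = mean_pi_level),
            class = "lesionmix_vpc")
}

#' Fraction of VPC cells whose observed proportion lies inside the PI
#'
#' @param x A [vpc()] result.
#' @export
vpc_coverage <- function(x) {
  s <- x$summary
  ok <- s$observed >= s$pi_lo & s$observed <= s$pi_hi
  mean(ok, na.rm = TRUE)
}

#' @export
print.lesionmix_vpc <- function(x, ...) {
  cat(sprintf("VPC: %d replicates, %d AUC bins, %.0f%% PI\n",
              x$n_reps, nrow(x$moments), 100 * x$pi_level))
  cat(sprintf("bin x category coverage: %.1f%%\n", 100 * vpc_coverage(x)))
  invisible(x)
}

#' @export
plot.lesionmix_vpc <- function(x, ...) {
  mo <- x$moments
  graphics::plot(mo$bin, mo$obs_mean, pch = 19, xlab = "AUC bin",
                 ylab = "mean lesion count",
                 ylim = range(c(mo$mean_lo, mo$mean_hi, mo$obs_mean)), ...)
  graphics::arrows(mo$bin, mo$mean_lo, mo$bin, mo$mean_hi,
                   angle = 90, code = 3, length = 0.03, col = "grey50")
  invisible(x)
}

#' Nonparametric bootstrap of a model fit
#'
#' Resamples subjects with replacement (optionally stratified by the arm of
#' first assignment), refits the model on every replicate starting from the
#' original estimates, and reports the replicate median and percentile 95%
#' confidence interval per parameter. Replicates that error or fail to
#' converge are counted; the result is flagged unreliable above 20%
#' failures.
#'
#' @param dataset Long-format dataset.
#' @param spec A [model_spec()].
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Seed controlling both resampling and refits.
#' @param fit Optional original fit (computed if omitted).
#' @param stratify_by_arm Stratify resampling by the subject's first-period
#'   arm (default TRUE).
#' @return Object of class `"lesionmix_boot"`: `replicates` matrix,
#'   `median`, `ci` (2.5/97.5 percentiles), `n_failed`, `reliable`.
#' @export
nonparametric_bootstrap <- function(dataset, spec, n_reps = 1000,
                                    seed = NULL, fit = NULL,
                                    stratify_by_arm = TRUE) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, nonparametric_bootstrap(
      dataset, spec, n_reps = n_reps, seed = NULL, fit = fit,
      stratify_by_arm = stratify_by_arm)))
  }
  validate_dataset(dataset)
  if (is.null(fit)) fit <- fit_model(dataset, spec, compute_se = FALSE)
  if (!fit$convergence) stop("original fit did not converge")
  first <- !duplicated(dataset$subject_id)
  ids <- dataset$subject_id[first]
  arm <- dataset$period_arm[first]
  rows_by_id <- split(seq_len(nrow(dataset)), dataset$subject_id)[
    as.character(ids)]

  reps <- matrix(NA_real_, n_reps, length(spec$params),
                 dimnames = list(NULL, spec$params))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    pick <- if (stratify_by_arm) {
      unlist(lapply(split(seq_along(ids), arm),
                    function(i) sample(i, length(i), replace = TRUE)),
             use.names = FALSE)
    } else {
      sample(seq_along(ids), length(ids), replace = TRUE)
    }
    idx <- unlist(rows_by_id[pick], use.names = FALSE)
    boot <- dataset[idx, ]
    boot$subject_id <- rep(seq_along(pick),
                           lengths(rows_by_id[pick]))
    res <- tryCatch(fit_model(boot, spec, init = fit$estimates,
                              compute_se = FALSE),
                    error = function(e) NULL)
    if (is.null(res) || !res$convergence) n_failed <- n_failed + 1L
    else reps[r, ] <- unlist(res$estimates)
  }
  ok <- stats::complete.cases(reps)
  ci <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  structure(list(replicates = reps, n_reps = n_reps,
                 median = apply(reps[ok, , drop = FALSE], 2, stats::median),
                 ci = ci, n_failed = n_failed,
                 reliable = n_failed <= 0.2 * n_reps,
                 original = unlist(fit$estimates)),
            class = "lesionmix_boot")
}

#' @export
print.lesionmix_boot <- function(x, digits = 4, ...) {
  cat(sprintf("Nonparametric bootstrap: %d replicates (%d failed)%s\n",
              x$n_reps, x$n_failed,
              if (!x$reliable) "  [flagged unreliable]" else ""))
  out <- data.frame(estimate = x$original, median = x$median,
                    ci_lo = x$ci[1, ], ci_hi = x$ci[2, ])
  print(out, digits = digits)
  invisible(x)
}
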