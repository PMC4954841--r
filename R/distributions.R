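# Candidate count distributions for per-visit lesion counts.
#
# All probability arithmetic is done in log space. The negative binomial is
# parameterized by its mean lambda and over-dispersion OVDP, so that
# Var(X) = lambda * (1 + OVDP * lambda); this is stats::dnbinom with
# size = 1/OVDP and mu = lambda. Below .OVDP_POISSON_LIMIT the NB is
# numerically singular (Gamma(1/OVDP) overflows) and the analytic Poisson
# limit is used instead.

.OVDP_POISSON_LIMIT <- 1e-8

.check_counts <- function(k) {
  if (length(k) == 0L) stop("'k' must be non-empty")
  if (any(!is.finite(k)) || any(k < 0) || any(k != floor(k))) {
    stop("'k' must contain non-negative integers")
  }
  invisible(k)
}

.check_lam <- function(lam) {
  if (any(!is.finite(lam)) || any(lam <= 0)) stop("'lam' must be > 0")
  invisible(lam)
}

.check_p0 <- function(p0) {
  if (any(!is.finite(p0)) || any(p0 < 0) || any(p0 >= 1)) {
    stop("'p0' must lie in [0, 1)")
  }
  invisible(p0)
}

.check_ovdp <- function(ovdp) {
  if (any(!is.finite(ovdp)) || any(ovdp < 0)) stop("'ovdp' must be >= 0")
  invisible(ovdp)
}

# log(exp(a) + exp(b)), elementwise, safe for -Inf
.logspace_add <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Poisson log probability mass
#'
#' @param k Vector of non-negative integer counts.
#' @param lam Mean parameter \eqn{\lambda > 0} (recycled against `k`).
#' @return Log-probabilities, finite for all valid inputs.
#' @examples
#' poisson_logpmf(0, 1) # -1
#' @export
poisson_logpmf <- function(k, lam) {
  .check_counts(k); .check_lam(lam)
  stats::dpois(k, lam, log = TRUE)
}

#' Zero-inflated Poisson log probability mass
#'
#' A point mass `p0` at zero mixed with a Poisson(`lam`) component. The
#' `k = 0` branch, \eqn{P_0 + (1-P_0) e^{-\lambda}}, is evaluated by
#' log-sum-exp.
#'
#' @inheritParams poisson_logpmf
#' @param p0 Inflated zero proportion in `[0, 1)`.
#' @export
zip_logpmf <- function(k, lam, p0) {
  .check_counts(k); .check_lam(lam); .check_p0(p0)
  n <- max(length(k), length(lam), length(p0))
  k <- rep_len(k, n); lam <- rep_len(lam, n); p0 <- rep_len(p0, n)
  out <- log1p(-p0) + stats::dpois(k, lam, log = TRUE)
  z <- k == 0L
  if (any(z)) {
    out[z] <- .logspace_add(log(p0[z]), log1p(-p0[z]) - lam[z])
  }
  out
}

#' Negative binomial log probability mass (mean / over-dispersion form)
#'
#' @inheritParams poisson_logpmf
#' @param ovdp Over-dispersion parameter \eqn{\ge 0}; the variance is
#'   `lam * (1 + ovdp * lam)`. Values below `1e-8` use the Poisson limit.
#' @export
nb_logpmf <- function(k, lam, ovdp) {
  .check_counts(k); .check_lam(lam); .check_ovdp(ovdp)
  n <- max(length(k), length(lam), length(ovdp))
  k <- rep_len(k, n); lam <- rep_len(lam, n); ovdp <- rep_len(ovdp, n)
  out <- numeric(n)
  pois <- ovdp < .OVDP_POISSON_LIMIT
  if (any(pois)) out[pois] <- stats::dpois(k[pois], lam[pois], log = TRUE)
  if (any(!pois)) {
    out[!pois] <- stats::dnbinom(k[!pois], size = 1 / ovdp[!pois],
                                 mu = lam[!pois], log = TRUE)
  }
  out
}

#' Zero-inflated negative binomial log probability mass
#'
#' @inheritParams nb_logpmf
#' @inheritParams zip_logpmf
#' @export
zinb_logpmf <- function(k, lam, ovdp, p0) {
  .check_counts(k); .check_lam(lam); .check_ovdp(ovdp); .check_p0(p0)
  n <- max(length(k), length(lam), length(ovdp), length(p0))
  k <- rep_len(k, n); lam <- rep_len(lam, n)
  ovdp <- rep_len(ovdp, n); p0 <- rep_len(p0, n)
  out <- log1p(-p0) + nb_logpmf(k, lam, ovdp)
  z <- k == 0L
  if (any(z)) {
    out[z] <- .logspace_add(log(p0[z]),
                            log1p(-p0[z]) + nb_logpmf(0L, lam[z], ovdp[z]))
  }
  out
}

#' Log probability mass for any of the four candidate families
#'
#' @inheritParams zinb_logpmf
#' @param family One of `"poisson"`, `"zip"`, `"nb"`, `"zinb"`.
#' @export
count_logpmf <- function(k, lam, ovdp = 0, p0 = 0,
                         family = c("nb", "poisson", "zip", "zinb")) {
  family <- match.arg(family)
  switch(family,
         poisson = poisson_logpmf(k, lam),
         zip     = zip_logpmf(k, lam, p0),
         nb      = nb_logpmf(k, lam, ovdp),
         zinb    = zinb_logpmf(k, lam, ovdp, p0))
}

#' Sample lesion counts
#'
#' Draws from the selected family. The negative binomial draw is the
#' gamma-mixed Poisson with shape `1/ovdp` and mean `lam`; zero inflation
#' overwrites a draw with 0 with probability `p0`. Uses R's RNG; seed at the
#' call site (e.g. `withr::with_seed`) for reproducibility.
#'
#' @param n Number of draws; `lam`, `ovdp`, `p0` are recycled to length `n`.
#' @inheritParams count_logpmf
#' @return Integer vector of counts.
#' @export
rcount <- function(n, lam, ovdp = 0, p0 = 0,
                   family = c("nb", "poisson", "zip", "zinb")) {
  family <- match.arg(family)
  .check_lam(lam)
  if (family %in% c("nb", "zinb")) .check_ovdp(ovdp) else ovdp <- 0
  if (family %in% c("zip", "zinb")) .check_p0(p0) else p0 <- 0
  lam <- rep_len(lam, n); ovdp <- rep_len(ovdp, n); p0 <- rep_len(p0, n)
  x <- integer(n)
  pois <- ovdp < .OVDP_POISSON_LIMIT
  if (any(pois)) x[pois] <- stats::rpois(sum(pois), lam[pois])
  if (any(!pois)) {
    x[!pois] <- stats::rnbinom(sum(!pois), size = 1 / ovdp[!pois],
                               mu = lam[!pois])
  }
  infl <- p0 > 0 & stats::runif(n) < p0
  x[infl] <- 0L
  as.integer(x)
}
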