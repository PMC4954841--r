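# Synthetic ADVANCE-like cohort generator.
#
# Three arms (placebo / 125 mcg every-2-weeks / 125 mcg every-4-weeks), MRI
# at weeks 0/24/48/96, placebo re-randomized 1:1 to the two active regimens
# at week 48, completely-at-random dropout with the published per-arm totals,
# lognormal clearance -> AUCss, two-subpopulation mixture NB counts with
# first-order drug-effect onset (Gd+) or duration-proportional means (T2).

.DATASET_COLS <- c("subject_id", "period_arm", "visit_day", "t_active_days",
                   "auc_ss", "count", "interval_days", "dropout_flag")

#' Trial design of the simulated study
#'
#' Defaults follow the analyzed ADVANCE cohort: 497/510/498 subjects in the
#' placebo / every-2-week (q2w) / every-4-week (q4w) arms (1505 total), MRI
#' at weeks 0, 24, 48 and 96, placebo re-randomized 1:1 to q2w/q4w at week
#' 48, 44/74/62 first-year dropouts (placebo/q2w/q4w) and 59/75 second-year
#' dropouts among q2w/q4w continuers.
#'
#' @param arm_sizes Named integer vector `(placebo, q2w, q4w)`.
#' @param visit_weeks MRI schedule in weeks, strictly increasing from 0.
#' @param year1_dropout Named dropouts `(placebo, q2w, q4w)` during year 1.
#' @param year2_dropout Named dropouts `(q2w, q4w)` among active-arm
#'   continuers during year 2.
#' @param rerandomize_week Week at which placebo switches to active drug.
#' @return A list of class `"lesionmix_design"`.
#' @export
trial_design <- function(arm_sizes = c(placebo = 497, q2w = 510, q4w = 498),
                         visit_weeks = c(0, 24, 48, 96),
                         year1_dropout = c(placebo = 44, q2w = 74, q4w = 62),
                         year2_dropout = c(q2w = 59, q4w = 75),
                         rerandomize_week = 48) {
  stopifnot(all(arm_sizes > 0), all(diff(visit_weeks) > 0),
            visit_weeks[1] == 0,
            all(year1_dropout >= 0), all(year2_dropout >= 0))
  if (any(year1_dropout > arm_sizes[names(year1_dropout)])) {
    stop("year-1 dropout exceeds arm size")
  }
  structure(list(arm_sizes = arm_sizes, visit_weeks = visit_weeks,
                 year1_dropout = year1_dropout, year2_dropout = year2_dropout,
                 rerandomize_week = rerandomize_week),
            class = "lesionmix_design")
}

#' Simulate individual clearance values
#'
#' Lognormal stand-in for the post-hoc clearance distribution of the
#' population PK model (individual values are not published). The defaults
#' (geometric mean 8.5 L/h, log-SD 0.35) center AUCss near ~15 ng·h/mL for
#' every-4-week and ~30 ng·h/mL for every-2-week dosing.
#'
#' @param n Number of subjects.
#' @param cl_geomean Geometric-mean clearance (L/h).
#' @param cl_logsd Log-scale standard deviation.
#' @export
simulate_clearance <- function(n, cl_geomean = 8.5, cl_logsd = 0.35) {
  stopifnot(n > 0, cl_geomean > 0, cl_logsd >= 0)
  stats::rlnorm(n, log(cl_geomean), cl_logsd)
}

#' Simulate an ADVANCE-like lesion-count trial
#'
#' Assigns arms, draws clearance and hence AUCss, draws each subject's
#' subpopulation and baseline activity from the mixture, computes per-visit
#' means via the exposure/onset structural model, samples negative binomial
#' counts with the subpopulation-specific over-dispersion, and censors visits
#' after a uniformly drawn dropout time honouring the per-arm dropout totals.
#' Baseline MRI precedes the first dose, so `t_active_days = 0` and
#' `auc_ss = 0` at week 0 in every arm; re-randomized placebo subjects
#' restart `t_active_days` at their first active dose.
#'
#' @param design A [trial_design()].
#' @param params Simulation truth, e.g. [final_params()]; needs `mu1`, `R`,
#'   `theta`, `sigma2`, `ovdp_low`, `ovdp_high`, `beta` and (Gd+) `t_half`.
#' @param endpoint `"gd"` (per-visit Gd+ counts, including baseline) or
#'   `"t2"` (new/enlarging T2 counts per inter-MRI interval).
#' @param cl_geomean,cl_logsd Clearance distribution, see
#'   [simulate_clearance()].
#' @param seed Optional integer; when given the whole dataset is
#'   bit-reproducible.
#' @return Long-format `data.frame` with columns `subject_id`, `period_arm`,
#'   `visit_day`, `t_active_days`, `auc_ss`, `count`, `interval_days`
#'   (`NA` for Gd+), `dropout_flag`; the per-subject simulation truth
#'   (arm, clearance, subpopulation, baseline mean) is attached as
#'   `attr(, "truth")`.
#' @export
simulate_trial <- function(design = trial_design(),
                           params = final_params(endpoint),
                           endpoint = c("gd", "t2"),
                           cl_geomean = 8.5, cl_logsd = 0.35,
                           seed = NULL) {
  endpoint <- match.arg(endpoint)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_trial(
      design = design, params = params, endpoint = endpoint,
      cl_geomean = cl_geomean, cl_logsd = cl_logsd, seed = NULL)))
  }
  n <- sum(design$arm_sizes)
  arm <- rep(names(design$arm_sizes), design$arm_sizes)
  id <- seq_len(n)

  cl <- simulate_clearance(n, cl_geomean, cl_logsd)
  # regimen after re-randomization: placebo splits 1:1, actives continue
  regimen <- arm
  plc <- which(arm == "placebo")
  half <- sample(plc, floor(length(plc) / 2))
  regimen[plc] <- "q4w"
  regimen[half] <- "q2w"
  n_doses <- ifelse(regimen == "q2w", 2, 1)
  auc_active <- compute_auc_ss(cl, n_doses)

  base <- draw_baseline_mixture(n, params)

  switch_day <- design$rerandomize_week * 7
  last_day <- max(design$visit_weeks) * 7
  # dropout day: NA = completer
  drop_day <- rep(NA_real_, n)
  for (a in names(design$year1_dropout)) {
    pick <- sample(which(arm == a), design$year1_dropout[[a]])
    drop_day[pick] <- stats::runif(length(pick), 0, switch_day)
  }
  for (a in names(design$year2_dropout)) {
    cand <- which(arm == a & is.na(drop_day))
    pick <- sample(cand, design$year2_dropout[[a]])
    drop_day[pick] <- stats::runif(length(pick), switch_day, last_day)
  }

  visit_day <- design$visit_weeks * 7
  if (endpoint == "gd") {
    vd <- visit_day
    interval <- rep(NA_real_, length(vd))
  } else {
    vd <- visit_day[-1]
    interval <- diff(visit_day)
  }
  nv <- length(vd)

  sub_i <- rep(id, each = nv)
  day <- rep(vd, times = n)
  intv <- rep(interval, times = n)
  arm_i <- rep(arm, each = nv)
  reg_i <- rep(regimen, each = nv)

  on_active <- arm_i != "placebo" | day > switch_day
  period_arm <- ifelse(on_active, reg_i, "placebo")
  t_active <- ifelse(arm_i == "placebo",
                     pmax(day - switch_day, 0),
                     day)
  # baseline MRI is pre-dose
  t_active[day == 0] <- 0
  auc <- ifelse(t_active > 0, rep(auc_active, each = nv), 0)

  lam0_i <- rep(base$lambda0, each = nv)
  lam <- lambda_trajectory(lam0_i, auc, t_active, params,
                           endpoint = endpoint, interval_days = intv)
  ovdp <- ifelse(rep(base$Y, each = nv) == 1L,
                 params$ovdp_low, params$ovdp_high)
  cnt <- rcount(length(lam), lam = lam, ovdp = ovdp, family = "nb")

  dropped <- rep(drop_day, each = nv)
  keep <- is.na(dropped) | day <= dropped
  out <- data.frame(subject_id = sub_i,
                    period_arm = period_arm,
                    visit_day = day,
                    t_active_days = t_active,
                    auc_ss = auc,
                    count = cnt,
                    interval_days = intv,
                    dropout_flag = as.integer(!is.na(dropped)))[keep, ]
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(subject_id = id, arm = arm,
                                   regimen = regimen, cl = cl,
                                   auc_active = auc_active,
                                   Y = base$Y, lambda0 = base$lambda0,
                                   drop_day = drop_day)
  attr(out, "endpoint") <- endpoint
  out
}

#' Validate a long-format lesion-count dataset
#'
#' Checks the documented schema; violations are reported with row numbers.
#'
#' @param x `data.frame` to validate.
#' @return `x`, invisibly, if valid.
#' @export
validate_dataset <- function(x) {
  missing_cols <- setdiff(.DATASET_COLS, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) {
      stop(sprintf("%s at row(s) %s", what,
                   paste(utils::head(i, 5), collapse = ", ")))
    }
  }
  bad(!is.finite(x$count) | x$count < 0 | x$count != floor(x$count),
      "invalid lesion count (must be a non-negative integer)")
  bad(!is.finite(x$auc_ss) | x$auc_ss < 0, "negative or missing auc_ss")
  bad(!is.finite(x$t_active_days) | x$t_active_days < 0,
      "negative or missing t_active_days")
  bad(!is.na(x$interval_days) & x$interval_days <= 0,
      "non-positive interval_days")
  invisible(x)
}

#' Write / read a lesion-count dataset
#'
#' Plain UTF-8 CSV with a header in the documented long-format schema;
#' `read_lesion_data()` validates on load, `write_lesion_data()` before
#' writing, so a write/read round trip is the identity.
#'
#' @param x Dataset as produced by [simulate_trial()].
#' @param path File path.
#' @export
write_lesion_data <- function(x, path) {
  validate_dataset(x)
  utils::write.csv(x[.DATASET_COLS], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lesion_data
#' @export
read_lesion_data <- function(path) {
  x <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.DATASET_COLS, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  # an all-NA interval column (Gd+ datasets) reads back as logical
  x$interval_days <- as.numeric(x$interval_days)
  validate_dataset(x)
  x
}
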