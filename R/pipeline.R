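# Pipeline entry points tying simulation, fitting and evaluation together.
# Each run writes its resolved configuration (including the seed) next to
# its outputs so every file is regenerable.

.write_config <- function(out_dir, config) {
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.ensure_dir <- function(out_dir) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  out_dir
}

#' Simulate a trial dataset and write it to disk
#'
#' @param out_dir Output directory (created if needed); receives
#'   `dataset.csv` and `config.json`.
#' @param endpoint `"gd"` or `"t2"`.
#' @param seed Integer seed; recorded in the config.
#' @param design A [trial_design()].
#' @param params Simulation truth (default [final_params()]).
#' @param cl_geomean,cl_logsd Clearance distribution.
#' @return The simulated dataset, invisibly.
#' @export
run_simulate <- function(out_dir, endpoint = c("gd", "t2"), seed = 1,
                         design = trial_design(),
                         params = final_params(endpoint),
                         cl_geomean = 8.5, cl_logsd = 0.35) {
  endpoint <- match.arg(endpoint)
  .ensure_dir(out_dir)
  dat <- simulate_trial(design, params, endpoint = endpoint,
                        cl_geomean = cl_geomean, cl_logsd = cl_logsd,
                        seed = seed)
  write_lesion_data(dat, file.path(out_dir, "dataset.csv"))
  .write_config(out_dir, list(stage = "simulate", endpoint = endpoint,
                              seed = seed, params = params,
                              cl_geomean = cl_geomean, cl_logsd = cl_logsd,
                              design = unclass(design)))
  invisible(dat)
}

#' Fit a model to a dataset file or data frame
#'
#' Writes a parameter table (`fit_<model>.csv`: parameter, estimate, SE,
#' RSE, transform) and a short text report.
#'
#' @param dataset Dataset path (CSV) or `data.frame`.
#' @param model `"M1"` ... `"M5"`.
#' @param endpoint `"gd"` or `"t2"`.
#' @param out_dir Optional output directory.
#' @param ... Passed to [fit_model()].
#' @return The [fit_model()] result.
#' @export
run_fit <- function(dataset, model = "M5", endpoint = c("gd", "t2"),
                    out_dir = NULL, ...) {
  endpoint <- match.arg(endpoint)
  if (is.character(dataset)) dataset <- read_lesion_data(dataset)
  spec <- model_spec(model, endpoint)
  fit <- fit_model(dataset, spec, ...)
  if (!is.null(out_dir)) {
    .ensure_dir(out_dir)
    utils::write.csv(parameter_table(fit),
                     file.path(out_dir, sprintf("fit_%s.csv", model)),
                     row.names = FALSE)
    rpt <- file.path(out_dir, sprintf("fit_%s.txt", model))
    withr::with_output_sink(rpt, print(fit))
  }
  fit
}

#' Run the evaluation suite for a fitted model
#'
#' Writes marginal-probability goodness of fit, the VPC summary, and
#' (optionally) nonparametric bootstrap results as CSV tables.
#'
#' @param dataset Dataset path or `data.frame` the model was fitted to.
#' @param fit A [fit_model()] result.
#' @param out_dir Optional output directory.
#' @param vpc_reps VPC simulation replicates (0 to skip).
#' @param boot_reps Bootstrap replicates (0 to skip).
#' @param seed Seed for the stochastic stages.
#' @return List with `gof`, `vpc`, `bootstrap` components.
#' @export
run_evaluate <- function(dataset, fit, out_dir = NULL, vpc_reps = 500,
                         boot_reps = 0, seed = 1) {
  if (is.character(dataset)) dataset <- read_lesion_data(dataset)
  obs <- observed_marginal_probs(dataset)
  prd <- predicted_marginal_probs(dataset, fit,
                                  max_count = max(dataset$count))
  gof <- merge(prd, obs, by = "count", all.x = TRUE,
               suffixes = c("_pred", "_obs"))
  gof$prob_obs[is.na(gof$prob_obs)] <- 0
  v <- if (vpc_reps > 0) vpc(dataset, fit, n_reps = vpc_reps, seed = seed)
  b <- if (boot_reps > 0) {
    nonparametric_bootstrap(dataset, fit$spec, n_reps = boot_reps,
                            seed = seed, fit = fit)
  }
  if (!is.null(out_dir)) {
    .ensure_dir(out_dir)
    utils::write.csv(gof, file.path(out_dir, "gof_marginal.csv"),
                     row.names = FALSE)
    if (!is.null(v)) {
      utils::write.csv(v$summary, file.path(out_dir, "vpc_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(v$moments, file.path(out_dir, "vpc_moments.csv"),
                       row.names = FALSE)
    }
    if (!is.null(b)) {
      utils::write.csv(data.frame(parameter = names(b$median),
                                  estimate = b$original,
                                  boot_median = b$median,
                                  ci_lo = b$ci[1, ], ci_hi = b$ci[2, ]),
                       file.path(out_dir, "bootstrap.csv"),
                       row.names = FALSE)
    }
  }
  list(gof = gof, vpc = v, bootstrap = b)
}

#' End-to-end reproduction on a synthetic cohort
#'
#' Simulates a trial at the published final-model estimates, fits the
#' requested model ladder, and tabulates OFV and the estimated exposure
#' slope per model (the model-comparison layout), optionally followed by
#' the evaluation suite for the final mixture model.
#'
#' @param endpoint `"gd"` or `"t2"`.
#' @param seed Integer seed driving every stochastic stage.
#' @param models Character vector of models to fit (default all five).
#' @param out_dir Optional output directory for the comparison table and
#'   per-stage outputs.
#' @param vpc_reps,boot_reps Evaluation options (0 to skip either).
#' @return List with `dataset`, `fits`, `comparison` and (if requested)
#'   `evaluation`.
#' @export
run_reproduce <- function(endpoint = c("gd", "t2"), seed = 1,
                          models = paste0("M", 1:5), out_dir = NULL,
                          vpc_reps = 0, boot_reps = 0) {
  endpoint <- match.arg(endpoint)
  truth <- final_params(endpoint)
  dat <- simulate_trial(params = truth, endpoint = endpoint, seed = seed)
  fits <- list()
  for (mdl in models) {
    t0 <- proc.time()[["elapsed"]]
    fits[[mdl]] <- fit_model(dat, model_spec(mdl, endpoint),
                             compute_se = FALSE)
    message(sprintf("%s: OFV %.1f (%.1fs)", mdl, fits[[mdl]]$ofv,
                    proc.time()[["elapsed"]] - t0))
  }
  comparison <- data.frame(
    model = models,
    ofv = vapply(fits, function(f) f$ofv, numeric(1)),
    slope_beta = vapply(fits, function(f) f$estimates$beta %||% NA_real_,
                        numeric(1)),
    converged = vapply(fits, function(f) f$convergence, logical(1)),
    row.names = NULL)
  out <- list(dataset = dat, fits = fits, comparison = comparison)
  if (!is.null(out_dir)) {
    .ensure_dir(out_dir)
    write_lesion_data(dat, file.path(out_dir, "dataset.csv"))
    utils::write.csv(comparison, file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    .write_config(out_dir, list(stage = "reproduce", endpoint = endpoint,
                                seed = seed, models = models,
                                truth = truth))
  }
  if ((vpc_reps > 0 || boot_reps > 0) && "M5" %in% models) {
    out$evaluation <- run_evaluate(dat, fits[["M5"]], out_dir = out_dir,
                                   vpc_reps = vpc_reps,
                                   boot_reps = boot_reps, seed = seed)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
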