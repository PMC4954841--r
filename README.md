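# lesionmix

Exposure–response models for longitudinal MRI lesion counts in
relapsing-remitting multiple sclerosis (RRMS) trials, written for
pharmacometricians and trial statisticians who need to relate steady-state
drug exposure to gadolinium-enhancing (Gd+) or new/enlarging T2 lesion
counts.

Lesion counts in RRMS trials mix an excess of structural zeros (many
patients show no lesions at any scan), a heavy right tail, and strong
within-patient correlation. `lesionmix` implements a ladder of five count
models culminating in a **two-subpopulation mixture negative binomial
mixed-effects model**: with probability θ a subject has low baseline
activity (mean μ₁, between-subject variance fixed to 0), otherwise high
activity with lognormal baseline (median μ₂ = R·μ₁, log-variance σ²), each
subpopulation with its own NB over-dispersion. Exposure enters as
steady-state AUC per four weeks, AUC_ss = DOSE·N/CL, acting log-linearly on
the mean with a first-order effect onset:

λ_ij = λ_i0 · exp( β · AUC_ij · [1 − exp(−ln2 · t_ij / t_half)] )

For interval-based T2 counts the onset term is dropped and the mean is
proportional to the observation-interval length. Marginal likelihoods over
the baseline random effect use a vectorized one-dimensional Laplace
approximation (the NONMEM-Laplacian idea); the mixture is marginalized
analytically. Diagnostics include marginal-probability goodness of fit,
AUC-binned visual predictive checks, and a nonparametric bootstrap. Because
no subject-level trial data are public, a synthetic ADVANCE-like cohort
generator (three arms 497/510/498, MRI weeks 0/24/48/96, placebo
re-randomized at week 48, published dropout totals) makes every stage
testable end to end.

## Worked example

Simulate a full-size Gd+ cohort at the published final-model estimates and
refit the mixture model:

```r
library(lesionmix)
dat <- simulate_trial(endpoint = "gd", seed = 1)
fit <- fit_model(dat, model_spec("M5", "gd"))
print(fit)
#> M5 fit (gd endpoint), 1505 subjects / 5455 observations
#> OFV (-2 log-likelihood): 11555.1   converged: TRUE
#>  parameter  estimate        se rse_pct transform
#>        mu1   0.48648  0.063026  12.956       log
#>          R   3.48036  0.567809  16.315       log
#>      theta   0.61592  0.020826   3.381     logit
#>   ovdp_low  46.77670  6.096468  13.033       log
#>  ovdp_high   0.49036  0.048152   9.820       log
#>       beta  -0.02437  0.003455  14.179  identity
#>     t_half 105.59841 44.165567  41.824       log
#>     sigma2   1.24049  0.145732  11.748       log
```

The fit recovers the simulation truth (μ₁ = 0.48, R = 3.53, θ = 0.602,
β = −0.0256, t_half = 115 d, σ² = 1.25) within its standard errors: about
62% of subjects fall in the low-activity subpopulation, and each additional
ln2/|β| ≈ 28 ng·h/mL of AUC_ss halves the expected lesion count once the
effect has fully set in. `run_reproduce(endpoint = "gd", seed = 1)` fits the
whole ladder M1–M5 and tabulates OFV per model; `vpc()` and
`nonparametric_bootstrap()` provide the simulation-based diagnostics. See
the vignette in `vignettes/exposure-response-methods.Rmd` for the model,
its assumptions, and the design choices.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package: the derived summary
identities of the final published models (weighted mean baseline count,
typical higher-activity baseline means for Gd+ and T2), and the
parameter-recovery experiments — simulating 1505-subject Gd+ and T2 cohorts
at the published estimates and refitting the mixture model by Laplace
maximum likelihood to recover the exposure slope, mixture proportion and
onset half-life. Results are written as JSON, one entry per quantity.
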