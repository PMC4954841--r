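Package: lesionmix
Title: Mixture Negative Binomial Exposure-Response Models for Longitudinal MRI Lesion Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exposure-response analysis of longitudinal gadolinium-enhancing (Gd+)
    and new/enlarging T2 MRI lesion counts against steady-state drug exposure
    (AUCss), as used in population PK/PD analyses of peginterferon beta-1a in
    relapsing-remitting multiple sclerosis. Provides numerically stable Poisson,
    zero-inflated Poisson, negative binomial and zero-inflated negative binomial
    count distributions; structural models combining log-linear or Emax exposure
    effects with a first-order effect-onset function; a ladder of five count
    models from naive pooled Poisson to a two-subpopulation mixture negative
    binomial mixed-effects model estimated by Laplace-approximated marginal
    maximum likelihood; a synthetic ADVANCE-like trial simulator; and
    simulation-based diagnostics (marginal-probability goodness of fit, visual
    predictive checks, nonparametric bootstrap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
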