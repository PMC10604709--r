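Package: adapopk
Title: Population Pharmacokinetics of Adalimumab in Inflammatory Bowel Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonlinear mixed-effects modelling of adalimumab trough
    concentrations in inflammatory bowel disease. Implements a
    one-compartment model with first-order absorption and linear
    elimination, a covariate model on apparent clearance (albumin as a
    power term, anti-adalimumab antibody status as a proportional
    shift), Laplace-approximate population fitting with optional
    informative priors (maximum a posteriori estimation), empirical
    Bayes individual prediction, leave-last-observation-out bias and
    imprecision metrics, prediction-corrected visual predictive checks,
    numerical predictive checks, normalized prediction distribution
    errors, case-resampling bootstrap validation, and a clinical-impact
    classification against the 8-12 mg/L therapeutic trough target.
    Includes a synthetic-cohort generator emulating a sparse
    therapeutic-drug-monitoring design so the full workflow can be
    exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
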