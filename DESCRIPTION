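Package: gcomp
Title: Parametric G-Formula Estimation for Sustained Treatment Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the effects of sustained (time-varying) treatment
    strategies on survival and end-of-follow-up outcomes from longitudinal
    data using the parametric g-formula. Fits parametric models for the
    joint distribution of time-varying covariates, discrete-time outcome
    hazards and competing-event hazards, and standardises over the covariate
    distribution under user-specified static, threshold, natural-course or
    custom dynamic interventions via Monte Carlo simulation. Includes
    nonparametric natural-course benchmarks for model diagnostics,
    subject-level bootstrap confidence intervals, a configuration-driven
    pipeline, and structural data-generating processes with exact
    counterfactual truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nnet,
    parallel
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    splines
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
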