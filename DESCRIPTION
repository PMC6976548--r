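Package: hazext
Title: Uncertainty in Extrapolated Parametric Survival Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how the choice of parametric survival model
    drives uncertainty in extrapolated hazard and survival functions,
    lifetime mean survival and cost effectiveness.  Implements seven
    commonly used survival families (exponential, Weibull, Gompertz, gamma,
    log-logistic, log-normal and generalised gamma) in a proportional-hazards
    style parameterisation, maximum-likelihood fitting under right censoring,
    exact, delta-method and multivariate-normal propagation of parameter
    uncertainty to hazard, survival and restricted-mean functionals,
    model-free hazard diagnostics (Kaplan-Meier, piecewise and kernel-smoothed
    hazards with bootstrap bands), a synthetic-data generator for four
    canonical hazard shapes, and a two-state Markov cohort cost-effectiveness
    model with probabilistic sensitivity analysis and expected value of
    perfect information.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    survival,
    MASS,
    jsonlite,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    flexsurv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
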