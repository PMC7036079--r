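Package: mabpk
Title: Population Pharmacokinetics of Monoclonal Antibody Trials by FOCE-I
Version: 0.1.0
Authors@R: person("mabpk", "maintainers", email = "mabpk@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of sparse serum concentration
    data from body-weight-dosed monoclonal antibody trials, built around a
    closed-form two-compartment intravenous-infusion model. Provides a
    first-order conditional estimation engine with eta-epsilon interaction
    (FOCE-I) for log-transformed concentrations, power/fractional/ratio
    covariate models on clearance and central volume, stepwise covariate
    modeling by likelihood-ratio testing, outlier and influence diagnostics
    based on conditional and individual weighted residuals, non-parametric
    subject-resampling bootstrap confidence intervals, visual predictive
    checks, and a clinical-trial simulator emulating a two-product
    parallel-group oncology study with per-cycle trough and post-infusion
    peak sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
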