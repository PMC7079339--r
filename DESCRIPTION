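Package: cisim
Title: Bistability and Combination Immunotherapy in Tumor-Immune Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic and stochastic models of cancer-immune system
    interaction. Implements a two-compartment tumor/effector base model with
    logistic tumor growth, mass-action killing and a net immunomodulation
    term, a variant with Michaelis-Menten saturation of effector
    proliferation and exhaustion, and a three-compartment model separating
    natural killer cells from cytotoxic T lymphocytes. Provides closed-form
    equilibrium and bistability analysis (quadratic and cubic root
    classification with killing-efficacy thresholds), numeric fixed-point
    location and linear stability for the three-compartment model,
    bifurcation sweeps over the killing efficacy, an adaptive tau-leaping
    stochastic simulator, and combination-immunotherapy experiments
    (stepwise killing-efficacy ramps and adoptive effector transfer,
    including dose-grid scans of treatment outcome).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
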