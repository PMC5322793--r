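Package: stochfit
Title: Fit Stochastic Reaction-Network Models to Single-Cell Distribution Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parameter estimation for stochastic chemical kinetics models from
    single-cell distribution data such as flow cytometry. Candidate parameter
    sets are screened by a deterministic precondition: the stable steady
    states of the ODE limit must match the number of modes of the measured
    distribution and bracket their locations, so that expensive stochastic
    simulation is only spent on promising candidates. Survivors are scored by
    a binned squared-difference distance between measured and simulated
    probability density functions, minimized by random search or a genetic
    algorithm. Ships an exact stochastic simulation engine with reproducible
    per-member seeding, multi-start steady-state location with eigenvalue
    stability classification, bundled models of constitutive gene expression
    and of the interferon-driven IRF7 positive-feedback circuit, generators
    for synthetic single-cell datasets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
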