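Package: rnevol
Title: Reaction-Norm Evolution with Evolvable Reference Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the evolution of phenotypic plasticity
    with the multivariate breeder's equation, where the reference environment of
    a parametric (polynomial cue-product) reaction norm is itself an evolvable
    mean trait. Provides Monte-Carlo propagation of the augmented population
    state under Gaussian stabilizing selection in a stationary stochastic
    environment with optional step changes, closed-form diagnostics for the
    variance-minimum environment and for positive-semidefiniteness bounds on the
    genetic covariance matrix, genetic-assimilation metrics, bundled experiment
    presets, YAML configuration round-tripping, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
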