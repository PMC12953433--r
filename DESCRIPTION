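Package: BayesMCA
Title: Bayesian Metabolic Control Analysis with Lin-Log Kinetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers posterior distributions over lin-log elasticity matrices
    from multi-strain proteomics, metabolomics and flux observations, and
    propagates them to flux control coefficients (FCCs) on a product-export
    flux to rank genetic intervention targets (overexpression or deletion).
    Includes stoichiometric model import (SBML and a JSON dialect), model
    reduction, exchange-rate estimation from fermentation time series,
    expression-constrained flux estimation (E-Flux2), mean-field automatic
    differentiation variational inference with adjoint gradients through the
    steady-state solve, posterior predictive checks, and a synthetic
    multi-omics data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    xml2,
    yaml,
    pracma,
    boot,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0)
biocViews: Metabolomics, Proteomics, Bayesian, NetworkInference,
    SystemsBiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
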