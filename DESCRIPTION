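Package: gcbnet
Title: Stochastic Gene Regulatory Network Models of Germinal Center B Cell
    Differentiation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and calibration of the BCL6-IRF4-BLIMP1 gene regulatory
    network driving germinal center (GC) B cell differentiation towards the
    plasmablast/plasma-cell (PB_PC) stage. The core model is a
    piecewise-deterministic Markov process with two-state bursty promoters whose
    switching rates respond to regulator proteins and to BCR/CD40 stimuli
    through products of Hill-type interaction factors. The package also provides
    the mean-field ordinary differential equation reduction with steady-state and
    bistability analysis, the kinetic ODE reference model, grid-search and
    one-dimensional sweep machinery for parameter calibration against single-cell
    expression distributions, a binned Kantorovich (1-Wasserstein) distance with a
    model-to-model variability study, and a generator of experiment-like
    single-cell qPCR datasets with stage-specific dropout structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    deSolve,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
biocViews: SystemsBiology, GeneRegulation, SingleCell, Network, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
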