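Package: calchain
Title: Sequential Bayesian Parameter Inference for Single-Cell Calcium
    Dynamics Along Cell Chains
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a four-variable ordinary differential equation model of
    ATP-stimulated cytosolic calcium dynamics to single-cell fluorescence
    traces by Markov chain Monte Carlo, transferring information between
    cells along "cell chains": orderings of cells (by transcriptional
    similarity, calcium-response similarity, or at random) in which each
    cell's posterior, after scaling and clipping, becomes the prior of its
    successor. Includes trace preprocessing (smoothing, truncation,
    downsampling, responder filtering), similarity-graph chain
    construction by depth-first search, convergence gating on the
    potential scale reduction of the log posterior with three-wise chain
    retention, within-posterior quantile-perturbation sensitivity
    analysis, and population-level analyses of fitted posteriors:
    focal-cell principal-component projection, gene-parameter correlation
    with Huber regression, Ward clustering of posterior means, Leiden
    clustering of expression, and marker-gene detection. A synthetic-data
    generator produces joint expression/trajectory populations with
    planted transcriptional states and gene-parameter couplings for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    MASS,
    Matrix,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
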