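Package: graphCox
Title: Network-Regularized Cox Proportional Hazards Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Penalized Cox proportional hazards modelling for
    high-dimensional gene-expression data with network-based
    regularizers. Implements a degree-weighted quadratic penalty in
    which well-connected genes are penalized less, a graph-Laplacian
    smoothness penalty, and the elastic net, all under one fitting
    interface with Breslow baseline-hazard estimation. Includes tools
    to build and normalize weighted gene co-expression networks from
    mutual correlation ranks, vertex centrality measures (weighted
    degree, betweenness, closeness) with ranking-comparison utilities,
    cross-validated partial-likelihood model selection, and a survival
    evaluation suite (deviance residuals, concordance index,
    prognostic-index risk stratification, Kaplan-Meier curves and
    log-rank tests). A synthetic-data generator produces networks,
    correlated expression matrices and right-censored survival times
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    igraph,
    survival,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    knitr
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'network.R'
    'centrality.R'
    'cox-likelihood.R'
    'penalties.R'
    'cox-fit.R'
    'evaluation.R'
    'model-selection.R'
    'synthetic.R'
    'io.R'
    'cli.R'
    'graphCox-package.R'
    'RcppExports.R'
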