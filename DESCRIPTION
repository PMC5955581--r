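Package: peernet
Title: Functional Networks and Peer Prediction for Calcium Imaging Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed functional networks from two-photon calcium
    fluorescence recordings of visual cortical populations using blocked
    three-variable partial correlations, assigns edge direction from
    cross-correlogram peak lags, characterizes directed triplet-motif
    clustering against Erdos-Renyi null ensembles, and predicts each
    neuron's single-trial fluorescence from its graph in-neighbours with a
    gain/offset-rescaled linear model benchmarked against LASSO-optimal
    weights. Includes dF/F0 preprocessing with a Savitzky-Golay baseline,
    orientation/direction tuning analysis with asymmetric circular Gaussian
    fits, and a synthetic-data generator emulating the drifting-grating
    recording regime so the whole pipeline is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    Matrix,
    methods,
    minpack.lm,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
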