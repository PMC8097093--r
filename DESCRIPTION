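Package: coadapt
Title: Simulating User-Interface Co-Adaptation in Body-Machine Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator for the coupled dynamics of a human learning to operate
    a dimensionality-reducing body-machine interface and of the interface
    adapting to the human. Models the user as a non-stationary multivariate
    Gaussian generative process updated by reward-weighted use-dependent
    learning (incremental principal-component tracking with reward-scaled
    learning rates and variance regularization), and the interface as a linear
    orthonormal-row map adapted by unsupervised incremental PCA. Provides a
    compiled simulation engine for single runs, playback of recorded sensor
    sequences and learning-rate grid experiments, performance metrics
    (planarity, principal subspace angle, variance accounted for, exponential
    convergence fitting), a synthetic generator of autocorrelated multichannel
    sensor data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
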