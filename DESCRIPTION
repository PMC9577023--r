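Package: fbmdropout
Title: Fractional Brownian Motion Dropout for Neural Network Regularization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spatially correlated dropout for artificial neural networks,
    modeled on the stochastic trajectories of brain serotonergic axons.
    Neuron layers are embedded in a Euclidean unit square as N x N grids of
    square cells; "fibers" -- sliding windows over superdiffusive fractional
    Brownian motion (FBM) paths with periodic boundary conditions -- silence
    every neuron they touch in each training iteration. Provides exact FBM
    sample-path generation (Davies-Harte circulant embedding with a Hosking
    fallback) with closed-form covariance oracles, the grid geometry and
    fiber dynamics, mask construction and fiber-count calibration to a target
    drop rate, and a small feed-forward network harness (MSE regression and
    softmax classification, Adam optimizer) to compare FBM-dropout against
    standard Bernoulli dropout and no dropout via generalization-gap
    trajectories. Includes a synthetic digit-glyph image generator and an
    MNIST IDX reader.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
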