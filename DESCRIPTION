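Package: elastnet
Title: Unsupervised Deep Displacement and Strain Estimation for Quasi-Static
    Ultrasound Elastography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quasi-static ultrasound strain elastography from
    radio-frequency (RF) frame sequences. Implements two displacement-estimation
    networks trained without ground-truth labels: a feed-forward encoder-decoder
    (USENet) and a recurrent variant with convolutional LSTM decoder blocks
    (ReUSENet) that carries memory across a compression sequence. Training
    minimises a three-term objective (local normalised cross-correlation
    similarity, an L1 penalty on the strain spatial gradient, and a temporal
    strain-consistency term). Axial strain is derived from displacement with a
    least-squares strain estimator. Includes an analytic speckle-phantom
    simulator with exact ground-truth deformation, elastographic evaluation
    metrics (NRMSE, SNRe, similarity/consistency, landmark TRE), an HDF5
    dataset container, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    rhdf5
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
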