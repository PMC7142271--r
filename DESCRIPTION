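Package: fcnet
Title: Functional Connectivity Networks and Image-Based Classification for
    Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Band-limited functional connectivity estimation for epoched
    multichannel EEG (coherence, Pearson correlation, phase-locking value,
    phase-lag index), small-world graph analysis of thresholded connectivity
    matrices against matched random-network nulls, encoding of connectivity
    matrices as square single- and three-channel images, and a small
    convolutional neural network classifier evaluated with subject-wise
    cross-validation. Includes a controllable synthetic multichannel signal
    generator with known band-specific phase coupling so the whole pipeline
    can be exercised and calibrated without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    jsonlite,
    generics,
    Rcpp,
    e1071,
    class,
    randomForest
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
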