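Package: sdmf
Title: Spatial Dynamic-Mode Features for Neural Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts spatial dynamic-mode (sDM) features from multichannel
    neurophysiological time series such as electrocorticography (ECoG).
    Trials are delay-embedded by Hankel stacking and decomposed with exact
    dynamic mode decomposition; the L2-normalized dynamic modes are turned
    into an explicit feature map whose inner products equal the Grassmann
    projection kernel, yielding per-channel (snDM) and channel-pair (seDM)
    features, optionally split by frequency band. Includes a synthetic
    signal generator with known ground truth, spectral power features for
    comparison, phase-randomized surrogates, and a nested cross-validated
    decoding harness (linear/kernel SVM, L1-regularized logistic
    regression, ridge regression) with reproducibility and selectivity
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    kernlab,
    glmnet,
    signal,
    data.table,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
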