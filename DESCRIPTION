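Package: crisprattn
Title: Attention-Boosted Models for CRISPR Guide Efficacy and Specificity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trainable deep models for CRISPR-Cas guide RNA design: an
    attention-plus-convolution classifier for off-target specificity of aligned
    sgRNA-DNA pairs, attention and CNN/LSTM hybrid regressors for on-target
    efficiency, a cell-specific network-weighted expression gene feature
    (NetExpress), shuffle-based input-feature importance, imbalance-aware
    training and evaluation protocols (oversampled mini-batches, k-fold and
    leave-group-out splits, AUC-ROC/PR-AUC/Spearman), and seeded synthetic-data
    generators with planted, recoverable signal so every component can be
    exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
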