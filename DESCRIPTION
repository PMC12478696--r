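Package: epiattn
Title: Enhancer-Promoter Interaction Prediction with a CNN-Transformer and
    Attention-Based Motif Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts enhancer-promoter interactions (EPIs) directly from paired
    DNA sequences with a convolutional feature extractor, a transformer block
    and a hierarchical attention layer, trained end to end with class-imbalance
    handling (shift augmentation or class-weighted cross-entropy). Beyond
    prediction, the package maps multi-head attention weights back to sequence
    windows, builds position weight matrices from convolutional activations,
    scores enhancer-region by promoter-region interactions, and exchanges
    motifs and hits with TOMTOM (MEME motif format) and BioGRID (TAB format)
    for transcription-factor interaction annotation. A synthetic planted-motif
    data generator makes the full pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
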