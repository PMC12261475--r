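Package: amyloscan
Title: Sliding-Window Detection of Amyloid Signaling Motifs with a
    Lightweight Bidirectional LSTM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains and applies a small bidirectional LSTM classifier for
    short amyloid signaling motifs (ASMs) in protein sequences. Provides
    fixed-width window extraction with background-frequency prepadding and
    zero postpadding, k-fold cross-validation ensembles whose per-window
    probabilities are averaged and max-pooled into per-sequence scores,
    evaluation metrics used for highly imbalanced motif retrieval (average
    precision, AUROC, interpolated recall at fixed false-positive rate,
    evidenced-set precision/recall/F1, retention rates), motif localization
    diagnostics, penultimate-layer embedding analysis, and a fully seeded
    synthetic motif-family benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
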