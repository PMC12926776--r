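Package: conflictMVPA
Title: Multivariate EEG Decoding of Conflict Processing Within and Across Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved and frequency-domain multivariate pattern analysis of
    EEG conflict processing. Implements regularized linear discriminant decoding
    with class-balanced cross-validation, electrode and frequency searchlights,
    cross-task temporal generalization, group-level permutation inference with
    threshold-free cluster enhancement (TFCE), resampled group null distributions
    for classification accuracy, JZS Bayes factors, and behavioral conflict-effect
    statistics. Ships a synthetic multi-subject EEG generator with planted
    conflict effects and a controllable cross-task overlap structure, so that
    the domain-general versus task-specific architecture question becomes a
    recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
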