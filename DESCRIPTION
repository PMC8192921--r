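Package: drivergene
Title: Driver Versus Passenger Gene Classification from DNA Sequence Moment Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Distinguishes cancer driver genes from passenger genes using only
    their raw DNA sequence. Each sequence is summarised as a fixed-length
    102-slot descriptor built from statistical moments (raw, central, and
    discrete Hahn) of a square-grid image of the encoded sequence and of 4x4
    position-relative incidence matrices, together with base composition and
    cumulative position vectors. Descriptors feed configurable classifier
    backends (random forest, RBF support vector machine, feed-forward neural
    network) evaluated with self-consistency, repeated independent-split, and
    stratified k-fold cross-validation protocols reporting sensitivity,
    specificity, accuracy, and the Matthews correlation coefficient, plus ROC
    curves with trapezoidal AUC. Includes a synthetic labeled-sequence
    generator for end-to-end testing and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
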