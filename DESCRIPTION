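Package: psprecg
Title: Probabilistic Symbolic Pattern Recognition for Short Single-Lead ECGs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening short (10-second) single-lead ECG recordings
    for early autonomic signatures of Parkinson's disease. Implements
    probabilistic symbolic pattern recognition (PSPR): signals are
    downsampled to a low symbol rate, discretized over a finite alphabet,
    summarized as pattern-transition probability models, and compared to a
    reference group through a weighted Euclidean dissimilarity, yielding one
    feature per modeled pattern length. Also provides the nine classical
    heart-rate characteristics from detected R peaks, nonparametric group
    comparisons, a backward-elimination logistic classifier with DeLong
    confidence intervals, a repeated stratified k-fold cross-validation
    protocol, and a fully seeded synthetic three-group ECG cohort generator
    for end-to-end testing without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
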