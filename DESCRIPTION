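Package: smrbci
Title: Simulation and Continual-Learning Decoding of Sensorimotor-Rhythm EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for four-class motor-imagery brain-computer interfacing on
    eight-channel sensorimotor-rhythm EEG. Provides a seed-reproducible
    synthetic EEG generator (1/f background, alpha rhythms, class-specific
    event-related desynchronization, trial protocols, session drift), the
    offline and causal online preprocessing chains, a CNN-Transformer
    (convolutional front-end plus multi-head self-attention) decoder with
    hand-derived backpropagation, action-observation-aware stratified
    cross-validation and sliding-segment augmentation, a closed-loop online
    phase with temporal smoothing, retry logic and domain-incremental
    fine-tuning, and ERD/ERS band-power quantification with paired
    nonparametric comparisons. Recordings are exchanged as European Data
    Format (EDF) files with tab-separated event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
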