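Package: speechtrf
Title: Neural Tracking of Continuous Speech with Boosted Temporal Response
    Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how strongly scalp EEG tracks acoustic
    and linguistic properties of continuous speech. Builds gammatone
    spectrogram and acoustic-onset predictors, information-theoretic
    phoneme-level predictors (n-gram surprisal and entropy, cohort-model
    word recognition with frequency or sentence-context priors), estimates
    multivariate temporal response functions (mTRFs) by L1
    coordinate-descent boosting with a Hamming-window lag basis and nested
    five-fold cross-validation, quantifies each predictor's unique
    contribution as the drop in Fisher-z prediction accuracy, and tests
    effects with cluster-mass permutation statistics. A synthetic-data
    module simulates trial-structured EEG from known kernels, n-back
    visual stimulus sequences, and toy lexicons with phoneme timelines,
    so the whole pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
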