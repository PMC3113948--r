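Package: emgdyn
Title: Surface EMG Pattern Recognition During Dynamic Contractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation pipeline for myoelectric pattern
    recognition during dynamic contractions. Generates protocol-faithful
    synthetic multi-channel surface EMG with ground-truth class and phase
    annotations, segments signals into overlapping analysis windows, extracts
    time-domain plus autoregressive (TD+AR) and wavelet-marginal (WT) feature
    sets, detects contraction onset with a Teager-Kaiser energy threshold
    calibrated under coverage constraints, classifies windows with LDA or
    Gaussian-kernel SVM (one-vs-one and one-vs-rest) fused by majority vote,
    and evaluates how the temporal composition of the training set (static
    hold only versus progressively more of the dynamic ramps) affects
    classification error under leave-one-session-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    signal,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
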