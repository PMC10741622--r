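Package: examEEG
Title: Spectral Power and Coherence Analysis of EEG Recorded During
    Simulated Oral Board Examinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative EEG analysis of clinical decision-making
    experiments in which participants undergo a timed, multi-phase simulated
    oral board examination while wearing a 14-channel wireless headset.
    Provides recording input/output (EDF+, XDF, and a diffable CSV fixture
    dialect), task segmentation from event markers, one-second epoching with
    threshold-based artifact rejection, Kaiser-window FFT power spectral
    density and magnitude-squared coherence over all 91 channel pairs per
    frequency band, eyes-open baseline correction and min-max normalization,
    behavioral scoring (weighted checklists, NASA-TLX, two-way random-effects
    intraclass correlation), expert-versus-novice group statistics, and
    Lasso-plus-OLS models linking connectivity features to performance and
    cognitive load. A synthetic cohort generator with analytically controlled
    band coherence provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    glmnet,
    jsonlite,
    data.table,
    xml2,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
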