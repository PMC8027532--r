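Package: eegcomplexity
Title: Multiscale Entropy and Spectral Scaling of Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for resting-state EEG signal complexity.
    Computes multiscale sample entropy over coarse-grained time scales,
    Welch power spectral density with robust 1/f power-law slope
    estimation, IAAFT phase-shuffled surrogate controls, mass-univariate
    group contrasts with threshold-free cluster enhancement (TFCE) and
    max-statistic permutation testing, and robust trimmed-mean bootstrap
    topography contrasts. Includes a synthetic multi-channel EEG cohort
    generator with controllable spectral exponents and irregularity for
    validation and power studies.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
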