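Package: painprint
Title: MALDI-TOF Serum Fingerprint Classification for Reflexive-Pain Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for classifying pathological-pain model
    cohorts from MALDI-TOF serum mass-spectrum fingerprints. Provides spectral
    preprocessing (Savitzky-Golay smoothing, loess baseline subtraction,
    normalization to 100% base peak, rigid peak alignment, peak detection,
    replicate merging and matrix-blank exclusion), variance-threshold feature
    selection with Z-scaling and PCA diagnostics, reflexive-pain behavioral
    endpoints (Hargreaves mean withdrawal latency and the von Frey up-down 50%
    threshold via the Dixon formula), and a seeded multilayer perceptron with a
    confidence-based reject option evaluated by leave-one-out cross-validation.
    A synthetic-cohort generator with known ground truth makes the full
    pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
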