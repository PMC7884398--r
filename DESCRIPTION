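Package: somlvq
Title: SOM-LVQ Classification of Tumors on Multiparametric MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise analysis of co-registered multiparametric MRI
    (T2-weighted, unenhanced T1-weighted, and arterial/venous-phase
    contrast-enhanced T1-weighted) for classifying renal tumors with and
    without sarcomatoid differentiation. Tumor voxel intensities are
    calibrated against the contralateral renal cortex and variance
    normalized, then quantized by a 9x9 Kohonen self-organizing map
    trained from scratch; each tumor is reduced to an 81-neuron
    "activation map" fingerprint that a learning vector quantization
    (LVQ1) classifier separates into the two classes. Includes exhaustive
    and subsampled leave-k-out cross-validation with balance-aware model
    selection, confusion-matrix metrics under a total-cohort denominator
    convention, a seeded synthetic phantom generator producing
    co-registered four-channel NIfTI cohorts with per-subject scanner
    gains and intra-tumor phenotype mixtures, and an end-to-end pipeline
    driver with provenance logging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
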