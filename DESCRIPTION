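Package: ramanstage
Title: Single-Cell Raman Spectral Preprocessing and PCA-LDA Staging of
    Oesophageal Disease Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A chemometrics pipeline for staging oesophageal adenocarcinoma
    progression from single-cell Raman spectra. Implements extended
    multiplicative signal correction (EMSC) with interferent (PDMS) removal,
    iterative morphological baseline correction, fingerprint-region
    truncation, Amide I normalization, Savitzky-Golay smoothing,
    variance-based outlier removal, and PCA-LDA classification with
    stratified k-fold cross-validation and confusion-matrix metrics. Ships a
    synthetic single-cell Raman spectrum generator emulating six
    disease-stage cell lines so the whole pipeline is testable without
    instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
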