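Package: bilispec
Title: Hierarchical Spectral Prediction of Total Bilirubin in Neonatal Whole Blood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts total bilirubin concentration in neonatal whole blood
    from visible-range transmission spectra using a hierarchical decision
    model: min-max normalization, reference-wavelength renormalization at
    605 nm, band-averaged slope statistics (alpha, beta) with clinical
    thresholds, and per-cohort quadratic calibration curves. Includes
    spectrum file I/O, model training and threshold calibration from
    labeled samples, evaluation utilities (sensitivity, specificity,
    test-set reproduction), a Beer-Lambert synthetic whole-blood spectrum
    generator for end-to-end testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
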