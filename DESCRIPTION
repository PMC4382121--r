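Package: glycoprof
Title: Quantification and Concordance Analysis of Serum N-Glycan
    HILIC-UHPLC Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for quantifying whole-serum N-glycan profiles from
    2-aminobenzamide labelled HILIC-UHPLC fluorescence chromatograms.
    Covers trace normalization, highest-peak time alignment, peak and
    trough detection from kernel-smoothed first and second derivatives,
    perpendicular-drop integration, glucose-unit calibration against a
    glucose homopolymer ladder, cross-sample peak matching by
    hierarchical clustering with a presence filter and position
    imputation, and the downstream concordance statistics: log-scale
    coefficients of variation, pairwise Pearson correlation,
    (1 - |r|) complete-linkage clustering, principal coordinate
    analysis, and per-peak blocked analysis of variance. A synthetic
    chromatogram generator with exact ground truth supports end-to-end
    validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    KernSmooth,
    ape,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
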