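Package: immunecensus
Title: Whole-Body Immune Cell Census with Lognormal Uncertainty Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the total number, mass and tissue distribution of the
    eleven major immune cell types in ICRP reference humans. Turns per-tissue
    cell-density evidence (histology, flow cytometry, multiplexed imaging,
    methylome deconvolution) into per-gram densities, fills gaps by
    cross-species and tissue-group extrapolation, combines methods by
    inverse-variance weighting in log space, and propagates multiplicative
    (lognormal) errors analytically and by bootstrap with correlated error
    groups. Includes a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    metafor,
    withr
Config/testthat/edition: 3
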