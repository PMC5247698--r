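Package: steatomorph
Title: Liver Steatosis Morphometry from H&E Field Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies hepatic steatosis from calibrated H&E-stained field
    images as the measured fat proportionate area (mFPA): fat vacuoles are
    segmented by RGB channel thresholding with connected-component area and
    circularity filters standing in for manual artifact editing, and pooled
    over randomly sampled fields per biopsy. Companion morphometry computes
    hepatocyte area from perpendicular diameters (oval model), lobule radius
    from portal-tract-to-central-vein distances, and hepatocytes per lobule
    under a hexagonal lobule model. Cohort statistics relate mFPA brackets
    to liver biochemistry with non-parametric tests, Spearman correlations
    and ROC cut-off analysis. A synthetic-histology module generates
    ground-truthed field images and cohorts so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
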