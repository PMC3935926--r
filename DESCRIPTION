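Package: seroshave
Title: Resampling-Based Autoantibody Biomarker Selection for Case-Control
    Protein Microarrays
Version: 1.0.0
Authors@R:
    person("seroshave", "authors", email = "seroshave@example.org",
           role = c("aut", "cre"))
Description: Discovery of serum-autoantibody biomarker panels from
    case-control protein microarray experiments. Reads GenePix GPR/GAL
    (ATF) files, performs joint preprocessing (background correction,
    duplicate-spot aggregation, log2 transform, quantile normalisation)
    and replicate quality control, screens features with the minimum
    M-statistic (exact hypergeometric threshold test), selects features
    by random-forest gene shaving over resampled train/test subruns,
    builds frequency-of-selection panels, verifies panels by repeated
    random-forest classification, re-ranks all features by nearest
    shrunken centroids, and generates calibrated synthetic cohorts with
    planted case-elevated antibodies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
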