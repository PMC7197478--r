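Package: fuccicycle
Title: Continuous Cell Cycle Phase from FUCCI Imaging and Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize and predict continuous (circular) cell
    cycle phase from paired FUCCI reporter fluorescence and single-cell
    RNA-seq molecule counts. Includes quality filtering and quantile
    normalization of UMI count matrices, nucleus detection and
    background-corrected fluorescence scoring of well images, plate-effect
    correction and circular phase inference from EGFP/mCherry scores,
    cyclic-trend estimation per gene by L1 quadratic trend filtering on a
    circularized series with cross-validated penalty selection, permutation
    significance testing of cyclic trends, a supervised naive-Bayes grid
    predictor of continuous phase with leave-one-individual-out evaluation,
    adapters for comparing external cell-cycle orderings and scores, and a
    seeded synthetic-data generator for paired ground-truth experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    cluster,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
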