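Package: ateminer
Title: Identification of Adipose Tissue Expansion Genes from Developmental
    Nutrition Microarray Designs
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to identify genes of adipose tissue expansion (ATE) from a
    three-nutrition-arm by five-age factorial microarray design in mouse
    inguinal fat. Implements quantile normalization, a three-criterion
    signal/fold-change/t-test gene filter, K-means clustering of standardized
    expression profiles with phenotype-template matching, a directional Venn
    intersection cascade that isolates genes tracking fat-mass expansion, and
    correlation, percent-relative-cumulative-frequency (PRCF), and
    ANOVA/compact-letter-display association statistics. A calibrated
    synthetic-data generator emulates the phenotype structure of the
    lactation under-/over-nutrition design (group summary statistics,
    longitudinal adiposity tracking, leptin coupling and detection limits,
    pooled triplicate arrays) so that every pipeline stage is testable
    against planted ground truth. A reader for GEO series-matrix files allows
    the pipeline to run on deposited expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
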