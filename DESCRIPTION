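Package: crgwas
Title: Climatic-Resilience Indicators and Mixed-Model GWAS for Longitudinal
    Body-Temperature Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives climatic-resilience indicators (log-variance, lag-1
    autocorrelation and skewness of moving-window deviations, daily maximum
    temperature, heat-stress duration and heat-stress units, and normalized
    variance products) from regular 10-minute vaginal-temperature records of
    lactating sows, and tests them for association with SNP genotypes using a
    mixed linear model with leave-one-chromosome-out genomic relationship
    matrices (MLMA-LOCO). Includes LD pruning, REML variance-component
    estimation by eigendecomposition, Bonferroni, suggestive and
    chromosome-wise (effective-number-of-segments) significance thresholds,
    genomic-inflation diagnostics with confidence intervals, positional
    gene/QTL annotation around significant SNPs, and a calibrated
    synthetic-data generator so the full pipeline is testable without access
    to the original records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
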