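Package: mircluster
Title: Cluster-Level Analysis of Circulating miRNA qPCR Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for circulating microRNA qPCR panel data
    organised by genomic cluster. Reads raw cycle-threshold (CT) matrices,
    applies hemolysis quality control and global-mean -dCT normalisation,
    assigns miRNAs to chromosomal clusters by a 10 kb chaining rule
    (c14mc, c19mc, miR-17/92), compares group-wise Pearson correlation
    structure with the Jennrich test and ANOVA on coefficient sets,
    performs minimum-residual exploratory factor analysis with parallel
    analysis and oblimin rotation, builds row-mean cluster scores, and
    fits matched-pair mixed-effects regressions of birth outcomes on
    cluster scores. Includes a synthetic-cohort generator with recorded
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    grDevices,
    graphics,
    Matrix,
    lme4,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    optparse
Config/testthat/edition: 3
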