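Package: methylaging
Title: Age-Associated Differential Methylation from Whole-Genome
    Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising aging-related DNA methylation
    change in whole-genome bisulfite sequencing cohorts. Implements
    three complementary analyses over per-CpG methylated/unmethylated
    read counts: per-CpG linear regression of percent methylation on
    age with covariate adjustment (aDMP calling), a sliding-window
    age-course statistic that localises methylation change along the
    lifespan, and a smoothing-based two-group (young versus old)
    t-statistic caller for differentially methylated regions (aDMRs).
    Includes readers for Bismark-style cytosine reports, BED, GMT and
    sample-metadata tables, CpG-island shore/shelf and gene/TSS
    annotation, three-method overlap summaries, hypergeometric gene-set
    over-representation, and a seeded synthetic-cohort generator with a
    ground-truth ledger for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmerTest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
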