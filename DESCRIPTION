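Package: concordia
Title: Transcriptome-Proteome Concordance Analysis for Paired Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression, over-representation and functional-group
    concordance analysis for paired bulk transcriptome (RNA-seq counts) and
    proteome (label-free intensity) cohorts. Implements TMM scaling-factor
    normalization with a common-dispersion negative-binomial exact test for
    transcripts, Welch t-tests on log intensities for proteins with
    intensity-based missingness handling, binomial over-representation against
    a detected-feature reference with redundant-term merging, and set-level
    direction (continuity-corrected two-proportion) and magnitude (one-sample
    t) tests that classify transcript-protein coupling per functional group.
    Includes a seeded synthetic paired-cohort generator emulating the
    statistical structure of case-control lymphoblast studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
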