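Package: niptkit
Title: Read-Count Analysis for Non-Invasive Prenatal Testing
Version: 0.1.0
Authors@R:
    person("niptkit", "developers", email = "niptkit@example.org",
           role = c("aut", "cre"))
Description: Bin-level read-count analysis for whole-genome non-invasive
    prenatal testing (NIPT). Counts alignments into fixed-size autosomal
    bins, reduces between-sample variation with peak correction, two
    GC-bias corrections (weighted-bin and LOESS) and a chi-squared-based
    down-weighting of over-dispersed bins, predicts fetal trisomies with
    four statistics (standard Z-score, MAD-based Z-score, normalized
    chromosome value and a forward-selection regression-based Z-score),
    and scores control-group representativeness with a Match QC statistic.
    Includes a negative-binomial bin-count simulator so the whole pipeline
    is testable without sequencing data, plus a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    optparse,
    Rsamtools,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
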