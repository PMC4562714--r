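Package: stableref
Title: Discovery and Validation of Stable Reference Genes from RNA-Seq and
    RT-qPCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and validating RT-qPCR reference genes.
    Implements angular-regression size-factor normalization of RNA-Seq count
    matrices, maximum-likelihood selection of a stably expressed gene set
    under a two-state Gaussian tail-probability model, coefficient-of-variation
    and normality-test candidate filtering, in-silico PCR screening of primer
    specificity on transcript sequences, and a four-algorithm consensus
    stability ranking of qPCR cycle-threshold data (comparative delta-Ct,
    BestKeeper, NormFinder and geNorm, aggregated by geometric mean of ranks).
    Includes simulators that generate count matrices, Ct tables and toy
    transcriptomes with planted ground truth for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
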