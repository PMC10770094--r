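Package: methylepi
Title: Methylome Context Summaries and Multiplicative-Model Epistasis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying genetic interactions between DNA
    replication and DNA methylation mutants in zebrafish-style phenotype
    screens, and for summarizing whole-genome bisulfite sequencing
    methylomes by cytosine context (CG, CHG, CHH). Implements the
    multiplicative epistasis model (fitness normalization, expected
    double-mutant fitness, propagated error, log2 interaction score and
    alleviating/synthetic/non-interacting classification), context
    classification with CG strand merging, coverage/variant/non-zero site
    filters, replicate union and intersection summaries with median and
    m.a.d. statistics, a restoration-fraction metric for double mutants,
    TSS methylation meta-profiles, and a transparent CUSUM-segmentation
    caller for differentially methylated regions honoring maxDist,
    minCpGs, minCoverage, minMethDiff and FDR thresholds. A synthetic-data
    module generates genotype-structured methylomes and phenotype tables
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
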