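Package: tailbias
Title: Consensus Correction of 3'-Coverage Bias in RNA-Seq Differential
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Differential-expression analysis for 3'-biased bulk RNA-seq,
    as arises with degraded or QIAzol-extracted RNA. Implements a
    self-contained count pipeline (CPM filtering, trimmed-mean-of-M-values
    size factors, common negative-binomial dispersion, conditional exact
    test, Benjamini-Hochberg FDR) and three 3'-bias correction strategies
    -- 3'-window counting, length-binned renormalisation, and length-slope
    alignment of fold changes -- fused by a conservative per-gene consensus
    that only calls differential expression when all three methods agree.
    Also provides age-trend fold-change statistics with group-exclusive set
    intersection, hypergeometric overrepresentation analysis over GMT gene
    sets, a lifespan test battery (log-rank, Fisher exact on median
    lifespan, Wang-Allison on maximum lifespan), delta-delta-Ct qPCR
    concordance, and a synthetic-data generator with known ground truth so
    every stage is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
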