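Package: coregshift
Title: Genome-Wide Redistribution Analysis of a Chromatin Coregulator
    During Stress Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying how a chromatin coregulator
    (such as the histone acetyltransferase Gcn5) redistributes across
    genes during stress adaptation. Provides differential-expression and
    coregulator-dependency calling from replicated two-condition
    expression log-ratios, length-normalized metagene occupancy
    profiling from tiling-array ChIP signal, K-means clustering of
    positional binding profiles with correlation distance and
    cross-condition cluster matching, hypergeometric gene-set and
    cluster-composition enrichment, cross-species ortholog-overlap
    comparison, and a truth-labelled synthetic data generator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
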