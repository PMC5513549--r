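Package: gutswap
Title: Habitat-Exchange Gut Microbiome Simulation and Read-Source Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates 16S rRNA amplicon habitat-exchange experiments with known
    per-read provenance and analyses them end to end: barcode demultiplexing and
    quality filtering, greedy centroid OTU clustering at fixed identity thresholds
    with Needleman-Wunsch global alignment, alpha diversity (Chao1, Shannon,
    analytic rarefaction), community comparison (family-level aggregation, shared
    membership, Spearman/UPGMA clustering, Bray-Curtis, NMDS), and read-source
    attribution that classifies each read in a habitat-exchanged gut as indigenous
    gut, water, sediment, combinations thereof, or group-specific via pooled 99%
    identity re-clustering of fold-change-targeted families.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    vegan,
    ape,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
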