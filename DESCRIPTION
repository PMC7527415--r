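Package: regenet
Title: Regulator Enrichment from Data-Driven Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks transcription (co-)factors driving a differential gene
    signature by combining data-driven network inference with enrichment
    statistics. Builds weighted gene co-expression and co-methylation
    networks (unsigned correlation adjacency, topological overlap, adaptive
    tree-cut module detection, eigengene merging), infers directed
    TF-target gene regulatory networks with per-target random forests,
    scores each regulator by a one-tailed hypergeometric enrichment of its
    network targets in a gene set combined with its own differential
    evidence, and provides cross-layer integration statistics for paired
    expression and DNA methylation data (Illumina array beta values, probe
    QC, region- and gene-level aggregation, differential methylation,
    Spearman concordance, module overlap, classical MDS). Includes seeded
    synthetic-data generators with planted structure for end-to-end
    benchmarking, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
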