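Package: amelonet
Title: Somatic Mutation Filtration and Co-Expression Network Integration
    for Two-Hit Ordering Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative tumor-genomics pipeline for small paired
    tumor-normal cohorts. Calls somatic variants from paired read counts with
    a one-sided Fisher exact test, applies a four-stage filtration cascade
    (quality control, population rarity, predicted severity, and their
    intersection), builds a weighted gene co-expression network from scratch
    (soft-threshold selection, unsigned adjacency, topological overlap,
    module detection, module eigengenes, kME, module-trait correlation),
    performs hypergeometric GO over-representation with Benjamini-Hochberg
    adjustment and parent-term redundancy removal, and integrates mutations
    with the network: module membership, a TOM-thresholded sub-network, and
    a variant-allele-fraction ordering test of the two-hit model. Includes a
    synthetic-data generator emulating the statistical structure of a small
    multi-patient exome plus expression-array study, so the full pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
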