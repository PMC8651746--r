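Package: discage
Title: Network-Based Prioritization of Significant Cancer Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate cancer driver genes from somatic mutation
    data (MAF) and one or more gene interaction networks. Each gene receives a
    weighted mutation frequency reflecting the functional impact of its variant
    classifications; an asymmetric spreading-strength measure on the consensus
    (union) network then quantifies the mutation influence a gene receives from
    its neighbors, and the two are combined into a final score that ranks both
    frequently and infrequently mutated genes. Includes MAF preprocessing
    (variant-class whitelist, hypermutated-sample removal), overlap-coefficient
    link prediction with pathway-calibrated thresholding for network
    enrichment, ranking evaluation against driver-gene benchmarks (precision,
    discounted cumulative gain), and a seeded synthetic-cohort simulator with
    planted driver modules for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
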