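Package: netdriver
Title: Genetically Inferred Causal Gene Modules and Network Key Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrative framework for identifying genetically inferred
    causal gene coexpression modules and network key driver genes for a
    quantitative trait such as blood pressure. Implements weighted gene
    coexpression network construction (soft thresholding, topological
    overlap, dynamic dendrogram cutting, module eigengenes), module-trait
    association, SNP-set enrichment analysis of eQTL-mapped gene sets
    against GWAS summary statistics with LD pruning and permutation
    calibration, key driver detection on molecular interaction networks,
    subnetwork construction, and hypergeometric enrichment against
    literature, annotation, and cross-species knockout gene sets. Ships a
    synthetic multi-omic data generator with planted ground truth so every
    stage carries a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
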