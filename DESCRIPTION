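Package: cernaflow
Title: Differential Expression and ceRNA Network Inference for Two-Region RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested workflow for bulk RNA-seq studies of trigeminal neuropathic
    pain that profile two tissue regions (trigeminal ganglion and spinal trigeminal
    subnucleus caudalis) under nerve injury and sham conditions. Provides RPKM
    normalisation, threshold-based differential expression of mRNA, lncRNA and
    circRNA with Welch tests on log expression, cross-region and disease-category
    overlap accounting, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, degree-ranked hub extraction from
    protein-protein interaction networks, and competing endogenous RNA
    (miRNA-sponge) network inference combining a shared-miRNA hypergeometric
    statistic with expression-correlation and direction-concordance filters. A
    seeded synthetic-data module plants known differentially expressed genes and
    ceRNA triplets so every stage can be validated against ground truth without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
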