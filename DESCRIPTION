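Package: lncnets
Title: Age-Stratified Co-Expression Network Analysis of Long Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Weighted gene co-expression network analysis of long noncoding
    RNAs (lncRNAs) in two-colour microarray data from a 2x2 design (adult and
    elderly subjects, sepsis and control). Implements microarray probe
    reannotation against modern gene catalogs with a hierarchical
    classification of probes into protein-coding, pseudogene, lncRNA and
    poorly annotated classes; well-above-background detection filtering;
    UPGMA sample clustering on the most variable lncRNAs; differential
    expression calling as the conjunction of a SAM-style permutation test and
    a rank-product test; per-age-group soft-thresholded co-expression
    networks (adjacency, connectivity, topological overlap); cross-network
    differential-connectivity statistics and hub selection; lncRNA-pathway
    median-similarity scoring with hypergeometric term enrichment; and
    cis-neighbour correlation analysis. A synthetic-data generator with
    planted modules, fold-changes and age-specific wiring provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
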