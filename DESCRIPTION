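Package: fammod
Title: Protein Family Content Modules and Cross-Domain Breadth for Archaeal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative protein-family-content analysis for archaeal genome
    collections. Implements a genome quality-control cascade based on 38
    single-copy genes, ribosomal-protein alignment coverage and single-scaffold
    checks, ANI-threshold dereplication with representative selection,
    construction of family-by-genome presence/absence matrices from homology
    hit tables, detection of modules of co-occurring protein families by
    Jaccard-distance hierarchical clustering with a dendrogram cutoff, module
    taxonomic assignment by the median-genome rule, lineage-enrichment
    classification, and a cross-domain "breadth" statistic that flags
    bacterial-like families. A synthetic-data generator plants block-structured
    co-occurrence so the whole pipeline is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    igraph,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
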