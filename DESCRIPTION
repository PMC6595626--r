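Package: germOmics
Title: Stage-Resolved Transcriptome-Metabolome Integration for Seed
    Germination
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-course multi-omics studies of seed
    germination sampled over six developmental stages (dry seed through
    first true leaf). Implements piecewise-linear segmentation of the
    imbibition (water-uptake) curve; empirical noise-probability
    differential expression on FPKM matrices; K-means stage clustering
    with supercluster merging and single-stage gene detection; a weighted
    gene coexpression core (soft-threshold adjacency, topological overlap,
    module detection, eigengenes, module-stage statistics, hub genes);
    Fisher's exact category enrichment; two-step metabolite significance
    (single-component PLS VIP filter then Student's t-test); and targeted
    correlation network analysis (TCNA) ranking enzyme-family members
    against metabolite trajectories with exact-permutation Spearman
    p-values. A seeded synthetic-data generator reproduces the assumed
    statistical structure of the six-stage design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
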