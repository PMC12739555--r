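Package: atmnet
Title: Cell-Specific Network Subtyping and BMI-Linked Gene Modules in Adipose Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering body-mass-index associated gene modules in
    bulk adipose transcriptomes and for subtyping macrophages by per-cell
    gene-regulatory-network degree profiles. The bulk pipeline runs CPM
    normalization, differential expression, co-expression network
    construction, Multilevel community detection refined by a
    correlation-distance k-means over community feature vectors, module-BMI
    association, and PageRank/random-forest key-gene selection. The
    single-cell pipeline builds one cell-specific network per cell from a
    local neighborhood-overlap statistic, summarizes cells by their network
    degree matrix, clusters that matrix with a shared-nearest-neighbor graph,
    tests differential and featured degree genes, extracts subtype-specific
    regulatory networks by edge prevalence, and detects gene modules from
    random-walk graph embeddings with Gaussian-mixture clustering and
    hypergeometric enrichment. A synthetic-data generator supplies bulk
    cohorts, dependency-structured cell populations, scale-free interaction
    networks and term gene sets so the full workflow is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    mclust,
    randomForest,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
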