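Package: adhesomics
Title: Quantitative Adhesome Profiling, Active-Module Discovery and
    Lamina-Association Mapping
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for quantitative integrin-adhesome
    analysis in carcinoma cells: label-free proteomics preprocessing
    (replication filtering, robust linear regression normalisation, two-pass
    missing-value imputation with predictive mean matching, variance-gated
    differential testing), beta-uniform-mixture calibration of p-values into
    FDR-controlled node scores with maximum-weight connected subgraph
    (prize-collecting Steiner tree) active-module discovery, community
    detection by Girvan-Newman modularity and the constant Potts model with a
    Surprise-maximising resolution scan, hub cartography, hypergeometric
    over-representation annotation, DamID lamina-association profiling with
    GATC fragment windows and shuffle-based peak FDR, and masked Manders
    co-occurrence imaging metrics. A synthetic-data module generates every
    input type with known ground truth so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    MASS,
    yaml,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, Network, GraphAndNetwork, Epigenetics, Coverage
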