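Package: soilCNet
Title: Dissolved Organic Matter Fluorescence, Microbial Co-Occurrence
    Networks, and Soil Carbon Mineralization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline linking dissolved organic matter (DOM)
    fluorescence composition to soil carbon mineralization through
    microbial co-occurrence network complexity. Provides correction and
    Raman normalization of excitation-emission matrices (EEMs), scalar
    fluorescence indices (BIX, HIX, FI), non-negative trilinear PARAFAC
    decomposition with split-half Tucker-congruence validation and
    component library matching, OTU-table ordination and PERMANOVA,
    Spearman/FDR co-occurrence network inference with modularity-based
    module detection and module eigengenes, alkali-trap titration
    arithmetic for cumulative CO2-C mineralization, permutation
    random-forest importance and variance partitioning of mineralization
    drivers, and a seeded synthetic-data generator emulating a
    3-treatment x 8-replicate incubation design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    vegan,
    randomForest,
    jsonlite,
    yaml,
    pracma,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
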