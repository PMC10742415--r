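Package: selfGP
Title: QTL Mapping and Genomic Prediction in Selfing Breeding Populations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of biparental selfing breeding
    populations (F2-F4) of the kind used in medicinal-plant breeding
    programmes such as red perilla. Provides a crossover-level breeding
    scheme simulator with multi-trait genetic architectures, marker
    filtering and 0/1/2 recoding of biallelic SNPs, exact F_t two-locus
    segregation models with maximum-likelihood recombination-fraction
    estimation and Kosambi linkage maps smoothed across populations,
    composite interval mapping with permutation-derived LOD thresholds,
    genomic relationship matrices, single- and multi-trait GBLUP with
    REML variance components and genomic heritability, BayesB and
    multi-trait BayesC-pi whole-genome regression, genetic correlations,
    and repeated k-fold cross-validated prediction accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
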