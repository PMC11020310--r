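Package: stoichprot
Title: Proteome Allocation, Bayesian Local Biclustering, and Elemental
    Stoichiometry for Factorial Chemostat Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking quantitative proteomics to cellular elemental
    stoichiometry in factorial culture experiments. Provides peak-area
    filtering and normalization for protein-by-sample abundance tables,
    proteome allocation metrics (percent of total peak area for proteins and
    trait groups), a nonparametric Bayesian local biclustering model with a
    zero-enriched Polya urn prior and collapsed Gibbs sampling for grouping
    proteins by shared response patterns, two-way ANOVA and PERMANOVA
    variance partitioning of cell quotas, elemental ratios, and the proteome,
    and a synthetic-data generator that plants known bicluster structure and
    factor effects so that every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    vegan,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
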