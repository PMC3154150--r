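Package: epiForge
Title: Model-Free Evolution of Epistatic Case-Control SNP Datasets
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generates balanced case-control SNP datasets exhibiting a strong
    k-way genotype-disease interaction (k = 3, 4, 5) while minimizing lower-order
    marginal effects, without imposing a penetrance model. Datasets evolve under a
    mutation-only evolution strategy with Pareto-optimal survivor selection;
    objectives are Multifactor Dimensionality Reduction (MDR) accuracies per
    interaction order, optionally joined by a Hardy-Weinberg equilibrium
    chi-square deviation objective. Includes a random-search baseline with a
    streaming Pareto archive, elbow-style front capping, Euclidean-distance
    representative selection, a mutation-rate sweep harness, two-sample
    Hotelling's T-squared comparison of run representatives, and readers/writers
    for the MDR flat-file format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: GeneticVariability, SNP, GenomeWideAssociation, Epistasis,
    StatisticalMethod
RoxygenNote: 7.3.3
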