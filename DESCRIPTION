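Package: adnapop
Title: Population-Genetic Inference for Ancient DNA Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for ancient-DNA population genetics built
    around pseudohaploid genotype data: EIGENSTRAT input/output, Patterson
    f2/f3/f4-statistics with weighted block-jackknife standard errors,
    qpAdm-style admixture-proportion estimation with rank-test p-values and
    feasibility flags, READ-style pairwise-mismatch-rate relatedness
    classification, ancestry-covariance decay dating of pulse admixtures,
    projection principal component analysis of ancient individuals onto
    modern variation, and composite-likelihood fitting of multi-population
    demographic models to the joint site frequency spectrum. A fast
    coalescent simulator (splits, pulse admixtures, dated sampling) and
    generators for ancestry-mosaic chromosomes, pseudohaploid degradation
    and pedigree relative pairs supply synthetic data for validation by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
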