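Package: rvpath
Title: Pathway-Level Rare-Variant Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing predefined gene sets (pathways) for
    association with a dichotomous phenotype using rare-variant data.
    Implements two competing strategies: direct application of rare-variant
    burden statistics (the weighted-sum rank test with phenotype-permutation
    significance, and combined multivariate collapsing with asymptotic
    Hotelling T-squared significance) to the pooled SNPs of a set, and
    aggregation of gene-level rare-variant p-values via Fisher's combined
    probability test, a two-sample Kolmogorov-Smirnov test, and weighted-KS
    gene set enrichment analysis. Includes a mini-exome genotype and
    phenotype simulator, construction of benchmark gene-set collections with
    a spurious-association filter, and an evaluation harness computing
    empirical type I error, power, best-method calls and a logistic
    characterization of when each strategy wins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmnet,
    optparse,
    readr,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
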