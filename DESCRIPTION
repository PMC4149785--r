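Package: wildqg
Title: Pedigree and Genomic Quantitative Genetics for Wild Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating heritability, maternal genetic and
    environmental effects, and genetic correlations in wild study
    populations from three sources of relatedness: observational or
    marker-derived pedigrees (via the numerator relationship matrix) and
    dense SNP genotypes (via a 2pq-scaled genomic relatedness matrix).
    Includes readers and writers for PLINK text genotypes, GCTA-dialect
    GRM files and pedigree tables; SNP quality control and linkage
    disequilibrium decay profiling; an average-information REML engine
    for univariate and bivariate animal models with arbitrary
    covariance-structured random effects; an orchestration layer for
    age-class comparisons, pruned-data refits and marker-subsampling
    experiments; and a gene-dropping simulator that generates
    polygynous overlapping-generation pedigrees, linked genotypes and
    phenotypes with known variance components for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    data.table,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    tidyr,
    jsonlite
Config/testthat/edition: 3
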