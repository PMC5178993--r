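Package: metapheno
Title: Metaphenotype Construction and Family-Based Association Analysis
Version: 0.1.0
Authors@R: person("GAIT", "Methods", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds synthetic phenotypic variables ("metaphenotypes") from a
    matrix of correlated quantitative traits by independent component analysis
    (with principal component analysis as a reference method), and analyses
    them in extended pedigrees with a variance-components mixed model:
    heritability estimation by maximum likelihood and likelihood-ratio SNP
    association with Bonferroni correction. Includes genotype quality control,
    Bayesian-PCA imputation of missing phenotypes, pedigree kinship (with a
    gene-dropping Monte-Carlo oracle), cross-validated selection of the number
    of components, a simulator of family-structured multivariate phenotype
    studies, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
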