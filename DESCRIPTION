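Package: gcovpipe
Title: Shared Genetic Influences Between Longitudinal Behavioural Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying shared genetic influences between two
    longitudinally measured behavioural traits with genome-wide SNP data.
    Implements genetic-relationship-matrix (GRM) construction with GCTA-format
    serialisation, average-information REML for univariate, bivariate and
    gene-set partitioned variance components (SNP heritability, genetic
    correlations and covariances), rank-based inverse-normal phenotype
    transformation with effective-number-of-tests correction, gene-set
    heritability scans with correlated-measure meta-analysis, matched-gene-set
    permutation and age/trait meta-regression, and polygenic scoring from
    case/control discovery summary statistics including a liability-threshold
    polygenic-score power and genetic-covariance model. Synthetic genotype,
    annotation, longitudinal trait and disorder GWAS generators with known
    ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    metafor
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
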