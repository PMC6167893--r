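Package: svypath
Title: Survey-Weighted Regression and Life-Course Path Models for Genetic
    Epidemiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design-based analysis of genetic associations across the adult
    life course in complex-survey cohorts. Provides survey-weighted
    pseudo-maximum-likelihood linear and logistic regression with
    Taylor-linearization (sandwich) variance estimation over strata and
    primary sampling units, including subpopulation (domain) estimation;
    recursive path models over genotype, body mass index at ages 21/45/65
    and interval type-2-diabetes indicators, with factorized
    full-information estimation under age-monotone missingness, a
    Monte-Carlo EM option for non-monotone missing mediators, and
    direct/indirect/total effect decomposition with delta-method standard
    errors; weight-history quality control (unit standardization, lb/kg
    confusion detection, BMI bounds, exclusion-flow accounting);
    Hardy-Weinberg testing, additive allele coding, kinship-based
    relative pruning and single-variant VCF ingestion; American Diabetes
    Association glycemic classification; and a synthetic-cohort generator
    emulating two-stage stratified sampling with age oversampling so every
    stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
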