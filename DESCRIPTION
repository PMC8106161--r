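Package: ferromics
Title: Multi-Omics Association Discovery for a Continuous Phenotype
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Latent-variable discovery of microbiome, metabolome and
    transcriptome features associated with a continuous phenotype such as
    serum ferritin. Implements single-response orthogonal projections to
    latent structures (O-PLS) with leave-one-out Q2, permutation validation,
    VIP and FDR-based feature selection; two-block O2-PLS integration with
    cross-validated component selection and correlation-scaled loadings;
    Mnet (minimax concave + ridge) penalized regression with unpenalized
    covariates tuned by cross-validation; covariate-adjusted partial Spearman
    correlation, Mann-Kendall quartile trend tests and hypergeometric
    over-representation analysis; alpha/beta diversity, principal coordinate
    analysis and PERMANOVA; and a seeded synthetic-data generator that
    emulates coupled phenotype/omics cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
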