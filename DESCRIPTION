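Package: rvhglm
Title: Hierarchical Generalized Linear Models for Grouped Rare and Common
    Genetic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian hierarchical generalized linear modelling of
    multiple groups of rare and common genetic variants together with
    covariates. Each group of variants contributes a genetic score (a
    weighted burden of minor-allele dosages) whose group effect and
    per-variant weights are estimated simultaneously by an alternating
    EM-within-IWLS mode-finding algorithm, with half-Cauchy scale-mixture
    priors on the weights and weakly informative Gamma(0.5, 0.5) priors on
    the group and covariate effects. Includes the reduced models
    (fixed-scale, fixed-weights burden scores, and all-variants main
    effects), delta-method inference for adjusted per-variant effects,
    genotype and phenotype input handling with mean imputation, a simulator
    for heritability-calibrated variant effects with risk and protective
    directions, and a replicate engine for empirical power and type-I error
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
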