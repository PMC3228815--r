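# Synthetic-data generator for the power/type-I studies.
#
# Emulates the structure of a population-based resequencing study of one
# candidate gene: a mixed common/rare MAF spectrum, variants partitioned
# into groups, a 3-level ancestry factor plus age, sex and BMI covariates,
# two singleton common non-synonymous variants handled as covariates, a
# log-scale continuous trait with residual SD ~ 0.2 and a binary trait by
# median dichotomization. Genotypes are drawn independently under
# Hardy-Weinberg proportions (no linkage disequilibrium). Per-variant
# additive effects are sampled uniformly on [0, beta_h] with the upper
# bound calibrated so a group explains a target fraction h of the
# phenotypic variance, and each effect is sign-flipped to protective with
# probability p.neg.

#' Simulate a genotype dosage matrix under Hardy-Weinberg proportions
#'
#' `dosage_ij ~ Binomial(2, q_j)` independently across variants and
#' individuals.
#'
#' @param n number of individuals.
#' @param mafs vector of minor allele frequencies in (0, 0.5\].
#' @param seed optional RNG seed.
#' @return a `geno_matrix` with variant ids from `names(mafs)` (or
#'   `v1, v2, ...`).
#' @export
simulate_genotypes <- function(n, mafs, seed = NULL) {
  if (any(mafs <= 0 | mafs > 0.5)) stop("MAFs must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  J <- length(mafs)
  ids <- names(mafs) %||% paste0("v", seq_len(J))
  m <- vapply(seq_len(J), function(j) stats::rbinom(n, 2, mafs[j]), numeric(n))
  dimnames(m) <- list(paste0("s", seq_len(n)), ids)
  .new_geno_matrix(m, imputed = TRUE)
}

#' Draw a mixed common/rare MAF spectrum
#'
#' Common MAFs are Uniform(0.01, 0.5); rare MAFs are log-uniform between
#' the singleton frequency `1/(2 n_target)` and 0.01, mimicking the
#' strongly skewed site-frequency spectrum of resequencing data.
#'
#' @param n_common,n_rare number of common / rare variants.
#' @param n_target sample size fixing the rare lower bound.
#' @param seed optional RNG seed.
#' @return numeric vector of length `n_common + n_rare`.
#' @export
maf_spectrum <- function(n_common, n_rare, n_target = 3000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lo <- 1 / (2 * n_target)
  c(stats::runif(n_common, 0.01, 0.5),
    exp(stats::runif(n_rare, log(lo), log(0.01))))
}

#' Heritability-calibrated upper bound for variant effects
#'
#' With effects drawn uniformly on `[0, beta_h]` (sign flips do not change
#' the variance) and independent Hardy-Weinberg genotypes, the group's
#' genetic variance is `(beta_h^2 / 3) * sum(2 q (1 - q))`. Solving
#' `h = V_g / (V_g + sigma_e^2)` gives
#' `beta_h = sqrt(3 h sigma_e^2 / ((1 - h) sum_j 2 q_j (1 - q_j)))`.
#'
#' @param h target heritability of the group, in \[0, 1).
#' @param mafs the group's minor allele frequencies.
#' @param sigma_e residual standard deviation.
#' @return the non-negative scalar `beta_h`.
#' @export
compute_beta_h <- function(h, mafs, sigma_e = 0.2) {
  if (h < 0 || h >= 1) stop("'h' must lie in [0, 1)")
  if (h == 0) return(0)
  denom <- sum(2 * mafs * (1 - mafs))
  sqrt(3 * h * sigma_e^2 / ((1 - h) * denom))
}

#' Sample per-variant additive effects
#'
#' `beta_j = s_j u_j` with `u_j ~ Uniform(0, beta_h)` and `s_j = -1` with
#' probability `p_neg` (protective), `+1` otherwise.
#'
#' @param J number of variants.
#' @param beta_h upper bound from [compute_beta_h()].
#' @param p_neg probability of a protective (sign-flipped) effect.
#' @param seed optional RNG seed.
#' @return numeric effect vector of length `J`.
#' @export
simulate_effects <- function(J, beta_h, p_neg = 0, seed = NULL) {
  if (p_neg < 0 || p_neg > 1) stop("'p_neg' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(J, 0, beta_h)
  s <- ifelse(stats::runif(J) < p_neg, -1, 1)
  u * s
}

#' Simulate a continuous or binary phenotype
#'
#' The continuous trait is `y = eta + N(0, sigma_e^2)` with
#' `eta = covariate part + sum_j beta_j z_ij`; the binary trait codes the
#' individuals at or above the sample median of the continuous trait as 1
#' (prevalence 0.5 up to one individual for odd n).
#'
#' @param genotypes dosage matrix.
#' @param covariate_part numeric vector (the fixed part of the linear
#'   predictor; 0 if absent).
#' @param effects per-variant effect vector aligned with the genotype
#'   columns.
#' @param trait `"continuous"` or `"binary"`.
#' @param sigma_e residual SD of the continuous trait.
#' @param seed optional RNG seed.
#' @return list with `y` (the requested trait), `y_cont` (the underlying
#'   continuous trait) and `genetic_part`.
#' @export
simulate_phenotype <- function(genotypes, covariate_part = 0, effects,
                               trait = c("continuous", "binary"),
                               sigma_e = 0.2, seed = NULL) {
  trait <- match.arg(trait)
  if (sigma_e <= 0) stop("'sigma_e' must be positive")
  if (!is.null(seed)) set.seed(seed)
  z <- if (inherits(genotypes, "geno_matrix")) genotypes$dosage else as.matrix(genotypes)
  gpart <- drop(z %*% effects)
  y_cont <- covariate_part + gpart + stats::rnorm(nrow(z), 0, sigma_e)
  y <- if (trait == "binary") as.numeric(rank(y_cont, ties.method = "first") >
                                          nrow(z) / 2) else y_cont
  list(y = y, y_cont = y_cont, genetic_part = gpart)
}

#' Catalog of simulation scenarios
#'
#' Returns the scenario configurations of the simulation study: group
#' sizes, per-group heritabilities and protective-effect proportions for
#' the three-group design (scenarios a-f) and the six-group design
#' (scenarios a-d), at sample sizes 3008 (continuous-trait layout) or 1499
#' (binary-trait layout, with its own group sizes). Group 1 (three-group
#' design) and groups 1-2 (six-group design) hold common variants; the
#' remaining groups hold rare variants.
#'
#' @param name `"three_groups"` or `"six_groups"`.
#' @param scenario scenario letter (`"a"`..`"f"` / `"a"`..`"d"`).
#' @param n sample size, 3008 or 1499.
#' @return an object of class `"rv_scenario"`: a list with `n`, `J`, `h`,
#'   `p_neg`, `common` (logical per group), `sigma_e`, covariate and
#'   singleton-variant settings.
#' @export
scenario_catalog <- function(name = c("three_groups", "six_groups"),
                             scenario = "a", n = 3008) {
  name <- match.arg(name)
  if (!n %in% c(3008, 1499)) stop("'n' must be 3008 or 1499")
  if (name == "three_groups") {
    J <- if (n == 3008) c(10, 26, 44) else c(11, 16, 34)
    common <- c(TRUE, FALSE, FALSE)
    cfg <- list(
      a = list(h = c(0, 0.005, 0),     p_neg = c(0, 0, 0)),
      b = list(h = c(0, 0.007, 0),     p_neg = c(0, 0.4, 0)),
      c = list(h = c(0.005, 0.005, 0), p_neg = c(0, 0, 0)),
      d = list(h = c(0.007, 0.007, 0), p_neg = c(0.4, 0.4, 0)),
      e = list(h = c(0, 0.007, 0.007), p_neg = c(0, 0, 0)),
      f = list(h = c(0, 0.007, 0.007), p_neg = c(0, 0.4, 0.4)))
  } else {
    J <- if (n == 3008) c(5, 5, 13, 13, 22, 22) else c(5, 6, 8, 8, 17, 17)
    common <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
    cfg <- list(
      a = list(h = c(0, 0.005, 0, 0, 0.005, 0), p_neg = c(0, 0, 0, 0, 0, 0)),
      b = list(h = c(0, 0.007, 0, 0, 0.007, 0), p_neg = c(0, 0.4, 0, 0, 0.4, 0)),
      c = list(h = c(0, 0, 0.005, 0, 0.005, 0), p_neg = c(0, 0, 0, 0, 0, 0)),
      d = list(h = c(0, 0, 0.007, 0, 0.007, 0), p_neg = c(0, 0, 0.4, 0, 0.4, 0)))
  }
  if (!scenario %in% names(cfg))
    stop("unknown scenario '", scenario, "' for ", name)
  sc <- cfg[[scenario]]
  structure(list(name = name, scenario = scenario, n = n,
                 J = J, h = sc$h, p_neg = sc$p_neg, common = common,
                 sigma_e = 0.2,
                 covariate_effects = c(race2 = 0.10, race3 = 0.05,
                                       age = 0.002, sex = 0.10, bmi = 0.01),
                 singleton_mafs = c(cns1 = 0.02, cns2 = 0.03),
                 singleton_effects = c(cns1 = 0, cns2 = -0.10)),
            class = "rv_scenario")
}

#' @export
print.rv_scenario <- function(x, ...) {
  cat("Simulation scenario", paste0(x$name, "/", x$scenario),
      "(n =", paste0(x$n, ")"), "\n")
  print(data.frame(group = paste0("G", seq_along(x$J)), J = x$J,
                   type = ifelse(x$common, "common", "rare"),
                   h = x$h, p_neg = x$p_neg))
  invisible(x)
}

# covariate table of the default design: 3-level ancestry factor, age,
# sex, BMI
.simulate_covariates <- function(n) {
  race <- sample(c("race1", "race2", "race3"), n, replace = TRUE,
                 prob = c(0.2, 0.6, 0.2))
  data.frame(race = race,
             age = stats::runif(n, 18, 65),
             sex = stats::rbinom(n, 1, 0.5),
             bmi = stats::rnorm(n, 28, 5))
}

#' Simulate a complete study dataset for a scenario
#'
#' Draws the MAF spectrum, genotypes (grouped variants plus the two
#' singleton common variants), covariates and trait for one replicate of a
#' scenario. Per-group effects are calibrated with [compute_beta_h()].
#'
#' @param scenario an `"rv_scenario"` from [scenario_catalog()].
#' @param trait `"continuous"` or `"binary"`.
#' @param seed RNG seed for the replicate.
#' @return list with `genotypes` (`geno_matrix` of the grouped variants),
#'   `singletons` (dosage matrix of the two singleton variants), `pheno`
#'   (data.frame: `sample_id`, `y`, covariates), `groups` (named list),
#'   `beta_true`, `realized_h` (per-group realized variance fraction of the
#'   continuous trait) and `scenario`.
#' @export
simulate_scenario <- function(scenario, trait = c("continuous", "binary"),
                              seed = NULL) {
  trait <- match.arg(trait)
  if (!inherits(scenario, "rv_scenario")) stop("'scenario' must come from scenario_catalog()")
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n
  K <- length(scenario$J)
  gnames <- paste0("G", seq_len(K))

  mafs <- unlist(lapply(seq_len(K), function(k) {
    m <- if (scenario$common[k]) maf_spectrum(scenario$J[k], 0, n)
         else maf_spectrum(0, scenario$J[k], n)
    stats::setNames(m, paste0(gnames[k], "_v", seq_len(scenario$J[k])))
  }))
  groups <- split(names(mafs), rep(gnames, scenario$J))[gnames]

  geno <- simulate_genotypes(n, mafs)
  geno$group <- rep(gnames, scenario$J)
  singletons <- simulate_genotypes(n, scenario$singleton_mafs)$dosage
  rownames(singletons) <- rownames(geno$dosage)

  beta <- unlist(lapply(seq_len(K), function(k) {
    bh <- compute_beta_h(scenario$h[k], mafs[groups[[k]]], scenario$sigma_e)
    stats::setNames(simulate_effects(scenario$J[k], bh, scenario$p_neg[k]),
                    groups[[k]])
  }))

  cov <- .simulate_covariates(n)
  ce <- scenario$covariate_effects
  cov_part <- ce["race2"] * (cov$race == "race2") +
    ce["race3"] * (cov$race == "race3") +
    ce["age"] * cov$age + ce["sex"] * cov$sex + ce["bmi"] * cov$bmi +
    drop(singletons %*% scenario$singleton_effects)

  ph <- simulate_phenotype(geno, cov_part, beta, trait, scenario$sigma_e)
  pheno <- data.frame(sample_id = rownames(geno$dosage), y = ph$y, cov,
                      stringsAsFactors = FALSE)

  gvar <- vapply(gnames, function(k) {
    gp <- drop(geno$dosage[, groups[[k]], drop = FALSE] %*% beta[groups[[k]]])
    stats::var(gp)
  }, numeric(1))
  realized_h <- gvar / stats::var(ph$y_cont)

  list(genotypes = geno, singletons = singletons, pheno = pheno,
       groups = groups, beta_true = beta, realized_h = realized_h,
       scenario = scenario, trait = trait)
}

#' Write a simulated dataset to the package's TSV formats
#'
#' Emits `genotypes.tsv`, `phenotype.tsv` (covariates plus the two
#' singleton variant dosages), `groups.tsv` and `true_effects.tsv` into
#' `dir`.
#'
#' @param ds a dataset from [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(ds$genotypes, file.path(dir, "genotypes.tsv"))
  ph <- cbind(ds$pheno, as.data.frame(ds$singletons))
  utils::write.table(ph, file.path(dir, "phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gm <- data.frame(variant_id = unlist(ds$groups, use.names = FALSE),
                   group = rep(names(ds$groups),
                               vapply(ds$groups, length, 1L)))
  utils::write.table(gm, file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  te <- data.frame(variant_id = names(ds$beta_true),
                   beta = format(unname(ds$beta_true), digits = 17, trim = TRUE))
  utils::write.table(te, file.path(dir, "true_effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
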