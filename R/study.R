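# Replicate engine: empirical power and type-I error across methods.
#
# Methods compared per replicate on the same simulated dataset:
#   proposed         - multiplicative fit, group scales estimated
#   fixed_scale_0.5  - multiplicative fit, scales frozen at 0.5
#   weights_fixed    - burden-score model with b_j = mu_j (Simple-Sum when
#                      mu = 1)
#   all_variants_minp- per-variant main-effect model; a group's p-value is
#                      the unadjusted minimum over its variants
# Frequencies of p < alpha over converged replicates give empirical power
# for truly associated terms and the type-I error rate otherwise.

.study_methods <- c("proposed", "fixed_scale_0.5", "weights_fixed",
                    "all_variants_minp")

# assemble the per-replicate design once: drop non-segregating variants
# (as the real analyses do), dummy-expand covariates, add the singletons
.prep_replicate <- function(ds) {
  geno <- suppressMessages(drop_non_segregating(ds$genotypes))
  groups <- lapply(ds$groups, intersect, colnames(geno$dosage))
  sing <- ds$singletons[, apply(ds$singletons, 2, stats::var) > 0, drop = FALSE]
  covdf <- ds$pheno[, c("race", "age", "sex", "bmi")]
  covdf$race <- factor(covdf$race)
  X <- cbind(stats::model.matrix(~., covdf)[, -1, drop = FALSE], sing)
  list(y = ds$pheno$y, X = X, z = geno$dosage, groups = groups)
}

# fit one method on one prepared replicate; returns named p-value vector
.fit_method <- function(method, prep, family, control) {
  if (method == "all_variants_minp") {
    fit <- fit_all_variants(prep$y, prep$X, prep$z, family, control = control)
    p <- c(fit$p_values[colnames(prep$X)],
           vapply(prep$groups, function(gv) group_min_pvalue(fit, gv),
                  numeric(1)))
    conv <- fit$converged
  } else {
    sm <- switch(method, proposed = "estimated",
                 fixed_scale_0.5 = "fixed", weights_fixed = "weights_fixed")
    fit <- rvhglm(prep$y, covariates = prep$X, genotypes = prep$z,
                  groups = prep$groups, prior_means = 1, family = family,
                  scale_mode = sm, control = control)
    p <- c(fit$p_values[colnames(prep$X)], fit$group_p)
    conv <- fit$converged
  }
  attr(p, "converged") <- conv
  p
}

#' Run a power / type-I error study
#'
#' Simulates `n_replicates` datasets from a scenario (replicate r uses seed
#' `base_seed + r`), fits the requested methods on each, and tabulates the
#' frequency of `p < alpha` per term, method and threshold. Non-converged
#' fits are excluded from the frequencies and counted in `n_converged`.
#'
#' @param scenario an `"rv_scenario"` from [scenario_catalog()].
#' @param methods subset of `c("proposed", "fixed_scale_0.5",
#'   "weights_fixed", "all_variants_minp")`.
#' @param n_replicates number of simulation replicates.
#' @param base_seed base RNG seed.
#' @param trait `"continuous"` or `"binary"` (binomial family is used for
#'   the binary trait).
#' @param alpha significance thresholds.
#' @param control inner fit controls from [bhglm_control()].
#' @return a `"power_table"` data.frame with columns `scenario`, `trait`,
#'   `method`, `term`, `alpha`, `frequency`, `n_replicates`, `n_converged`.
#' @export
run_study <- function(scenario, methods = .study_methods, n_replicates = 200,
                      base_seed = 1, trait = c("continuous", "binary"),
                      alpha = c(0.05, 0.01, 0.001),
                      control = bhglm_control()) {
  trait <- match.arg(trait)
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  methods <- match.arg(methods, .study_methods, several.ok = TRUE)
  family <- if (trait == "binary") stats::binomial() else stats::gaussian()

  pvals <- vector("list", length(methods))
  names(pvals) <- methods
  conv <- stats::setNames(rep(0L, length(methods)), methods)
  for (r in seq_len(n_replicates)) {
    ds <- simulate_scenario(scenario, trait, seed = base_seed + r)
    prep <- .prep_replicate(ds)
    for (m in methods) {
      p <- .fit_method(m, prep, family, control)
      if (isTRUE(attr(p, "converged"))) {
        conv[m] <- conv[m] + 1L
        pvals[[m]] <- rbind(pvals[[m]], p)
      }
    }
  }

  out <- do.call(rbind, lapply(methods, function(m) {
    P <- pvals[[m]]
    do.call(rbind, lapply(alpha, function(a) {
      data.frame(scenario = paste0(scenario$name, "/", scenario$scenario),
                 trait = trait, method = m, term = colnames(P), alpha = a,
                 frequency = colMeans(P < a),
                 n_replicates = n_replicates, n_converged = conv[m],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))
  class(out) <- c("power_table", "data.frame")
  attr(out, "pvalues") <- lapply(pvals, function(P) {
    rownames(P) <- NULL
    P
  })
  out
}

# Wilson 95% score interval for a binomial proportion
.wilson <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = ctr - hw, upper = ctr + hw)
}

#' Compare methods on one term of a power table
#'
#' Sorts the methods by their significance frequency at one threshold and
#' attaches Wilson 95\% intervals; `significantly_ordered` is set when the
#' top two intervals are disjoint.
#'
#' @param table a `"power_table"` from [run_study()].
#' @param term the term to compare (e.g. `"G2"`).
#' @param alpha the threshold level to compare at.
#' @return data.frame sorted by decreasing frequency with columns `method`,
#'   `frequency`, `lower`, `upper` and attribute `significantly_ordered`.
#' @export
compare_methods <- function(table, term, alpha) {
  rows <- table[table$term == term & table$alpha == alpha, ]
  if (nrow(rows) < 2) stop("term '", term, "' at alpha ", alpha,
                           " present for fewer than 2 methods")
  ci <- t(mapply(function(f, n) .wilson(round(f * n), n),
                 rows$frequency, rows$n_converged))
  out <- data.frame(method = rows$method, frequency = rows$frequency,
                    lower = ci[, 1], upper = ci[, 2],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency), ]
  rownames(out) <- NULL
  attr(out, "significantly_ordered") <-
    nrow(out) >= 2 && out$lower[1] > out$upper[2]
  out
}

#' Write a power table as TSV
#'
#' @param table a `"power_table"`.
#' @param path output path.
#' @export
write_power_table <- function(table, path) {
  tab <- as.data.frame(table)
  tab$frequency <- format(tab$frequency, digits = 17, trim = TRUE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
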