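# The multiplicative hierarchical GLM: eta_i = beta0 + x_i'beta +
# sum_k g_k sum_{j in G_k} b_j z_ij. Group effects g_k and per-variant
# weights b_j are estimated jointly by alternating two conditional
# hierarchical GLMs: (7) given the weights, fit covariates and group
# effects on the genetic scores S_ik = sum_j b_j z_ij; (8) given the group
# effects and covariates (as an offset), fit the weights on the per-variant
# predictors g_k[j] * z_ij. One EM-IWLS step of each sub-model per outer
# iteration; one deviance sequence (from step 7) drives convergence.

# normalise groups input into a named list of variant-id vectors
.as_group_list <- function(groups, variant_ids) {
  if (is.data.frame(groups)) {
    if (!all(c("variant_id", "group") %in% names(groups)))
      stop("group data.frame needs columns 'variant_id' and 'group'")
    groups <- split(as.character(groups$variant_id), as.character(groups$group))
  } else if (!is.list(groups)) {
    if (length(groups) != length(variant_ids))
      stop("group label vector must have one entry per variant column")
    groups <- split(variant_ids, as.character(groups))
  }
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("G", seq_along(groups))
  groups <- lapply(groups, as.character)
  unknown <- setdiff(unlist(groups), variant_ids)
  if (length(unknown))
    stop("group(s) reference unknown variant id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  dup <- unlist(groups)[duplicated(unlist(groups))]
  if (length(dup))
    stop("variant(s) assigned to more than one group: ",
         paste(unique(dup), collapse = ", "))
  small <- names(groups)[vapply(groups, length, 1L) < 2]
  if (length(small))
    stop("group(s) with fewer than 2 variants: ", paste(small, collapse = ", "),
         "; pass singleton variants as covariates instead")
  groups
}

#' Genetic (burden) score of a variant group
#'
#' The weighted sum `S_i = sum_{j in group} b_j z_ij` collapsing a group of
#' variants into one predictor per individual.
#'
#' @param z dosage matrix with variant ids as column names.
#' @param b named weight vector (must cover `group`).
#' @param group character vector of variant ids.
#' @return numeric score vector, one entry per row of `z`.
#' @examples
#' z <- cbind(v1 = c(0, 1, 2), v2 = c(1, 0, 0))
#' genetic_score(z, c(v1 = 1, v2 = 1), c("v1", "v2"))  # row sums
#' @export
genetic_score <- function(z, b, group) {
  miss <- setdiff(group, colnames(z))
  if (length(miss)) stop("unknown variant id(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(group, names(b))
  if (length(miss)) stop("no weight for variant id(s): ", paste(miss, collapse = ", "))
  drop(z[, group, drop = FALSE] %*% b[group])
}

#' Adjusted per-variant effects with delta-method standard errors
#'
#' The per-variant adjusted main effect `theta_j = g * (b_j - mu_j)`
#' measures the deviation of variant j's contribution from the fixed-weight
#' baseline. Its standard error by the delta method (the conditional
#' alternating fit provides no cross-covariance between g and b, which is
#' therefore omitted) is
#' `SE^2 = g^2 Var(b_j) + (b_j - mu_j)^2 Var(g)`.
#' When the SE degenerates to zero (no deviation and a zero group effect
#' variance contribution), the p-value is reported as 1.
#'
#' @param g group effect estimate (scalar or per-variant vector).
#' @param g_se its standard error.
#' @param b per-variant weight estimates.
#' @param b_se their standard errors.
#' @param mu per-variant prior means.
#' @param df degrees of freedom for the Wald reference (`Inf` for a normal).
#' @return data.frame with columns `estimate`, `se`, `p`.
#' @examples
#' adjusted_effects(0.3, 0.1, 1.4, 0.2, 1)  # se = 0.0721
#' @export
adjusted_effects <- function(g, g_se, b, b_se, mu, df = Inf) {
  if (any(is.na(b_se)) || any(is.na(g_se))) stop("missing standard errors")
  theta <- g * (b - mu)
  se <- sqrt(g^2 * b_se^2 + (b - mu)^2 * g_se^2)
  p <- rep(1, length(theta))
  ok <- which(is.finite(se) & se > 0)
  if (length(ok))
    p[ok] <- mapply(function(est, s) wald_test(est, s, df)$p_value,
                    theta[ok], se[ok])
  data.frame(estimate = theta, se = se, p = p)
}

#' Fit the multiplicative hierarchical GLM for grouped variants
#'
#' Jointly estimates covariate effects, per-group effects `g_k` and
#' per-variant weights `b_j` in the model
#' `h(E[y_i]) = beta_0 + x_i' beta + sum_k g_k sum_{j in G_k} b_j z_ij`.
#' Weights carry half-Cauchy scale-mixture priors centred at prior means
#' `mu_j` (1 by default, or functional scores in (0, 1\]); group and
#' covariate effects carry weakly informative Gamma(0.5, 0.5)-variance
#' priors. Fitting alternates one EM-IWLS step of the group-effect model
#' and one of the weight model per outer iteration until the relative
#' deviance change falls below `tol`.
#'
#' `scale_mode` selects the model variant: `"estimated"` (the default)
#' estimates the group-specific half-Cauchy scales from the data;
#' `"fixed"` freezes them at `fixed_scale` (0.5 by default); and
#' `"weights_fixed"` pins `b_j = mu_j`, which reduces the model to a
#' hierarchical GLM on fixed burden scores (the Simple-Sum model when all
#' `mu_j = 1`, a Weighted-Sum model otherwise).
#'
#' @param y response vector, or a formula whose right-hand side names the
#'   covariates in `data` (e.g. `y ~ age + sex`).
#' @param covariates numeric covariate matrix (ignored when `y` is a
#'   formula). Singleton variants must be supplied here as extra columns;
#'   groups of size 1 are rejected.
#' @param genotypes imputed dosage matrix (individuals x variants, no
#'   missing values) with variant ids as column names, or a
#'   [geno_matrix][read_genotypes] object.
#' @param groups variant grouping: a named list of variant-id vectors, a
#'   data.frame with columns `variant_id` and `group`, or a label vector
#'   aligned with the genotype columns. Every group needs at least two
#'   variants.
#' @param prior_means per-variant prior weight means: a scalar, or a named
#'   vector over variant ids. Default 1.
#' @param family a family accepted by [check_family()].
#' @param scale_mode `"estimated"`, `"fixed"` or `"weights_fixed"`.
#' @param fixed_scale the frozen half-Cauchy scale under
#'   `scale_mode = "fixed"`.
#' @param data data.frame holding the response and covariates when `y` is a
#'   formula.
#' @param tol outer convergence tolerance.
#' @param max_outer maximum number of outer iterations.
#' @param control inner EM-IWLS controls from [bhglm_control()].
#' @return an object of class `"rvhglm"`; see [summary.rvhglm()] for the
#'   result table.
#' @examples
#' set.seed(7)
#' z <- matrix(rbinom(200 * 6, 2, 0.2), 200, 6,
#'             dimnames = list(NULL, paste0("v", 1:6)))
#' y <- 0.2 * rowSums(z[, 1:3]) + rnorm(200, sd = 0.5)
#' fit <- rvhglm(y, genotypes = z,
#'               groups = list(G1 = paste0("v", 1:3), G2 = paste0("v", 4:6)))
#' summary(fit)
#' @export
rvhglm <- function(y, covariates = NULL, genotypes, groups, prior_means = 1,
                   family = stats::gaussian(),
                   scale_mode = c("estimated", "fixed", "weights_fixed"),
                   fixed_scale = 0.5, data = NULL,
                   tol = 1e-5, max_outer = 200, control = bhglm_control()) {
  scale_mode <- match.arg(scale_mode)
  family <- check_family(family)
  cl <- match.call()

  if (inherits(y, "formula")) {
    if (is.null(data)) stop("a formula response requires 'data'")
    mf <- stats::model.frame(y, data)
    resp <- stats::model.response(mf)
    mm <- stats::model.matrix(attr(mf, "terms"), mf)
    covariates <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
    y <- resp
  }
  if (inherits(genotypes, "geno_matrix")) {
    if (anyNA(genotypes$dosage)) stop("genotypes contain missing values; impute first")
    if (missing(groups) && !all(is.na(genotypes$group))) groups <- genotypes$group
    genotypes <- genotypes$dosage
  }
  z <- as.matrix(genotypes)
  if (anyNA(z)) stop("genotypes contain missing values; impute first")
  if (is.null(colnames(z))) colnames(z) <- paste0("variant", seq_len(ncol(z)))
  if (missing(groups) || is.null(groups) ||
      (is.list(groups) && length(groups) == 0))
    stop("no variant groups supplied; use fit_all_variants() to model ",
         "per-variant main effects without group structure")
  groups <- .as_group_list(groups, colnames(z))
  K <- length(groups)
  varids <- unlist(groups, use.names = FALSE)
  z <- z[, varids, drop = FALSE]
  kmap <- rep(names(groups), vapply(groups, length, 1L))
  names(kmap) <- varids

  if (length(prior_means) == 1) {
    mu <- stats::setNames(rep(prior_means, length(varids)), varids)
  } else {
    miss <- setdiff(varids, names(prior_means))
    if (length(miss)) stop("no prior mean for variant(s): ", paste(miss, collapse = ", "))
    mu <- prior_means[varids]
  }
  if (any(!is.finite(mu))) stop("prior means must be finite")

  n <- length(y)
  Xc <- cbind("(Intercept)" = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
    Xc <- cbind(Xc, covariates)
  }
  nc <- ncol(Xc)

  # groups whose variants carry no variation can never get a group effect
  zvar <- apply(z, 2, stats::var)
  degen <- vapply(groups, function(g) all(zvar[g] == 0), logical(1))
  if (any(degen))
    warning("group(s) with constant genetic score: ",
            paste(names(groups)[degen], collapse = ", "),
            "; group effect reported as 0 with SE = Inf")
  act <- names(groups)[!degen]
  if (length(act) == 0) stop("no estimable group effects")

  score_mat <- function(b) {
    S <- vapply(groups[act], function(g) drop(z[, g, drop = FALSE] %*% b[g]),
                numeric(n))
    colnames(S) <- act
    S
  }
  tags7 <- c("intercept", rep("coef", nc - 1 + length(act)))

  s_fixed8 <- if (scale_mode == "fixed") fixed_scale else control$s_fixed
  control8 <- control
  control8$s_fixed <- s_fixed8

  if (scale_mode == "weights_fixed") {
    b <- mu
    S <- score_mat(b)
    fit7 <- bhglm(cbind(Xc, S), y, family, tags = tags7,
                  control = control)
    b_se <- stats::setNames(rep(NA_real_, length(varids)), varids)
    fit8 <- NULL
    trace <- fit7$deviance_trace
    converged <- fit7$converged
    n_outer <- fit7$n_iter
  } else {
    b <- mu
    state7 <- NULL
    state8 <- NULL
    trace <- numeric(0)
    converged <- FALSE
    dev_prev <- Inf
    fit7 <- fit8 <- NULL
    for (outer in seq_len(max_outer)) {
      S <- score_mat(b)
      fit7 <- bhglm(cbind(Xc, S), y, family, tags = tags7,
                    control = control, n_steps = 1, state = state7)
      state7 <- fit7$state
      gk <- fit7$coefficients[act]
      offset8 <- drop(Xc %*% fit7$coefficients[seq_len(nc)])
      gvec <- stats::setNames(rep(0, length(varids)), varids)
      gvec[names(kmap)] <- ifelse(kmap %in% act, gk[kmap], 0)
      U <- sweep(z, 2, gvec, "*")
      control8$dispersion <- fit7$dispersion
      if (!is.null(state8)) state8$phi <- fit7$dispersion
      fit8 <- bhglm(U, y, family, tags = rep("weight", length(varids)),
                    prior_mean = mu, weight_group = kmap, offset = offset8,
                    control = control8, n_steps = 1, state = state8)
      state8 <- fit8$state
      b <- fit8$coefficients
      trace <- c(trace, fit7$deviance)
      if (abs(fit7$deviance - dev_prev) / (abs(fit7$deviance) + 0.1) < tol) {
        converged <- TRUE
        break
      }
      dev_prev <- fit7$deviance
    }
    n_outer <- length(trace)
    b_se <- fit8$std_errors
  }

  cf7 <- fit7$coefficients
  beta <- cf7[seq_len(nc)]
  beta_se <- fit7$std_errors[seq_len(nc)]
  beta_p <- fit7$p_values[seq_len(nc)]
  g <- stats::setNames(rep(0, K), names(groups))
  g_se <- stats::setNames(rep(Inf, K), names(groups))
  g_p <- stats::setNames(rep(1, K), names(groups))
  g[act] <- cf7[act]
  g_se[act] <- fit7$std_errors[act]
  g_p[act] <- fit7$p_values[act]
  g_p_bh <- stats::setNames(bh_adjust(g_p), names(g_p))

  S_final <- score_mat(b)
  eta <- drop(Xc %*% beta) + drop(S_final %*% g[act])
  fitted <- family$linkinv(eta)

  # adjusted per-variant effects with delta-method SEs
  gj <- g[kmap]
  gj_se <- g_se[kmap]
  if (scale_mode == "weights_fixed") {
    adj <- data.frame(estimate = rep(0, length(varids)),
                      se = rep(0, length(varids)), p = rep(1, length(varids)))
  } else {
    adj <- adjusted_effects(gj, gj_se, b, b_se, mu, df = fit7$df)
  }
  rownames(adj) <- varids

  # multiplicative-decomposition identity: g * sum(b z) must equal
  # g * sum(mu z) + sum(g (b - mu) z), individual by individual
  fixed_part <- vapply(groups[act],
                       function(gv) drop(z[, gv, drop = FALSE] %*% mu[gv]),
                       numeric(n))
  lhs <- drop(S_final %*% g[act])
  rhs <- drop(fixed_part %*% g[act]) +
    drop(z %*% (gj * (b - mu)))
  eq6_max_dev <- max(abs(lhs - rhs))

  structure(list(coefficients = beta, std_errors = beta_se, p_values = beta_p,
                 group_effects = g, group_se = g_se, group_p = g_p,
                 group_p_bh = g_p_bh,
                 weights = b, weight_se = b_se, prior_means = mu,
                 adjusted = adj, scores = S_final, groups = groups,
                 group_of = kmap, degenerate_groups = names(groups)[degen],
                 family = family, scale_mode = scale_mode,
                 fixed_scale = if (scale_mode == "fixed") fixed_scale else NULL,
                 dispersion = fit7$dispersion, df = fit7$df,
                 deviance = fit7$deviance, deviance_trace = trace,
                 converged = converged, n_outer = n_outer,
                 eq6_max_dev = eq6_max_dev,
                 eta = eta, fitted = fitted, y = y,
                 X_covariates = Xc, genotypes = z,
                 call = cl),
            class = "rvhglm")
}

#' @export
print.rvhglm <- function(x, ...) {
  cat("Multiplicative hierarchical GLM for grouped variants\n")
  cat("  family:", x$family$family, "(", x$family$link, "link );",
      "scale mode:", x$scale_mode, "\n")
  cat("  n =", length(x$y), "; groups:",
      paste(sprintf("%s (J=%d)", names(x$groups),
                    vapply(x$groups, length, 1L)), collapse = ", "), "\n")
  cat("  outer iterations:", x$n_outer,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("\nGroup effects:\n")
  print(data.frame(estimate = x$group_effects, se = x$group_se,
                   p = signif(x$group_p, 3), p_bh = signif(x$group_p_bh, 3)))
  invisible(x)
}

#' Result table for a multiplicative fit
#'
#' One row per model term: the intercept and covariates, the group effects
#' (with raw and Benjamini-Hochberg adjusted p-values), then per group the
#' estimated weights and the adjusted per-variant effects (with delta-method
#' SEs and the total per-variant effect `g * b_j` in `total_effect`).
#' `lower2se`/`upper2se` are `estimate -/+ 2 se`.
#'
#' @param object an `"rvhglm"` fit.
#' @param ... unused.
#' @return a data.frame with columns `term`, `kind`, `group`, `estimate`,
#'   `se`, `lower2se`, `upper2se`, `p`, `p_bh`, `total_effect`.
#' @export
summary.rvhglm <- function(object, ...) {
  row <- function(term, kind, group, est, se, p, p_bh = NA_real_,
                  total = NA_real_) {
    data.frame(term = term, kind = kind, group = group,
               estimate = est, se = se,
               lower2se = est - 2 * se, upper2se = est + 2 * se,
               p = p, p_bh = p_bh, total_effect = total,
               stringsAsFactors = FALSE)
  }
  cn <- names(object$coefficients)
  out <- row(cn, c("intercept", rep("covariate", length(cn) - 1)),
             NA_character_, unname(object$coefficients),
             unname(object$std_errors), unname(object$p_values))
  out <- rbind(out, row(names(object$group_effects), "group_effect",
                        names(object$group_effects),
                        unname(object$group_effects), unname(object$group_se),
                        unname(object$group_p), unname(object$group_p_bh)))
  for (k in names(object$groups)) {
    ids <- object$groups[[k]]
    out <- rbind(out,
                 row(ids, "weight", k, unname(object$weights[ids]),
                     unname(object$weight_se[ids]), NA_real_),
                 row(ids, "adjusted_effect", k,
                     object$adjusted[ids, "estimate"],
                     object$adjusted[ids, "se"],
                     object$adjusted[ids, "p"],
                     total = unname(object$group_effects[k] *
                                    object$weights[ids])))
  }
  rownames(out) <- NULL
  class(out) <- c("summary.rvhglm", "data.frame")
  out
}

#' @export
print.summary.rvhglm <- function(x, digits = 4, ...) {
  y <- x
  class(y) <- "data.frame"
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits)
  print(y)
  invisible(x)
}

#' @export
coef.rvhglm <- function(object,
                        which = c("all", "covariates", "groups", "weights"),
                        ...) {
  which <- match.arg(which)
  switch(which,
         covariates = object$coefficients,
         groups = object$group_effects,
         weights = object$weights,
         all = c(object$coefficients, object$group_effects, object$weights))
}

#' @export
fitted.rvhglm <- function(object, ...) object$fitted

#' @export
residuals.rvhglm <- function(object,
                             type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted; fam <- object$family
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(fam$variance(mu)),
         deviance = sign(y - mu) * sqrt(pmax(fam$dev.resids(y, mu, rep(1, length(y))), 0)))
}

#' Predict from a multiplicative fit
#'
#' @param object an `"rvhglm"` fit.
#' @param newdata optional list with elements `covariates` (matrix, same
#'   columns as at fit time, or `NULL` when the model had none) and
#'   `genotypes` (dosage matrix containing all grouped variant columns).
#'   When omitted, the training-data predictions are returned.
#' @param type `"link"` for the linear predictor, `"response"` for the mean.
#' @param ... unused.
#' @export
predict.rvhglm <- function(object, newdata = NULL,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$eta
  } else {
    z <- as.matrix(newdata$genotypes)
    n <- nrow(z)
    Xc <- cbind("(Intercept)" = rep(1, n))
    if (ncol(object$X_covariates) > 1) {
      cv <- as.matrix(newdata$covariates)
      Xc <- cbind(Xc, cv[, colnames(object$X_covariates)[-1], drop = FALSE])
    }
    act <- setdiff(names(object$groups), object$degenerate_groups)
    S <- vapply(object$groups[act],
                function(gv) genetic_score(z, object$weights, gv), numeric(n))
    eta <- drop(Xc %*% object$coefficients) +
      drop(S %*% object$group_effects[act])
  }
  if (type == "link") eta else object$family$linkinv(eta)
}

#' Simulate responses from a fitted multiplicative model
#'
#' @param object an `"rvhglm"` fit.
#' @param nsim number of response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with `nsim` simulated response columns.
#' @export
simulate.rvhglm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  n <- length(mu)
  draw <- switch(object$family$family,
                 gaussian = function() stats::rnorm(n, mu, sqrt(object$dispersion)),
                 binomial = function() stats::rbinom(n, 1, mu),
                 poisson  = function() stats::rpois(n, mu),
                 Gamma    = function() stats::rgamma(n, shape = 1 / object$dispersion,
                                                     scale = mu * object$dispersion))
  out <- as.data.frame(replicate(nsim, draw()))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Effect plot of a multiplicative fit
#'
#' Point estimates with +/- 2 SE bars for the covariates and group effects
#' (left) and the adjusted per-variant effects grouped by variant group
#' (right), in the style of a forest plot.
#'
#' @param x an `"rvhglm"` fit.
#' @param ... passed to [graphics::plot].
#' @export
plot.rvhglm <- function(x, ...) {
  s <- summary(x)
  keep <- s$kind %in% c("covariate", "group_effect", "adjusted_effect")
  s <- s[keep, ]
  s <- s[is.finite(s$se), ]
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  idx <- rev(seq_len(nrow(s)))
  graphics::plot(s$estimate, idx, xlim = range(c(s$lower2se, s$upper2se)),
                 yaxt = "n", xlab = "estimate (+/- 2 SE)", ylab = "",
                 pch = 19, ...)
  graphics::segments(s$lower2se, idx, s$upper2se, idx)
  graphics::abline(v = 0, lty = 3, col = "grey50")
  graphics::axis(2, at = idx, labels = s$term, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Write / read a multiplicative result table as TSV
#'
#' The table from [summary.rvhglm()] is written with its fixed column set;
#' `read_rvhglm_tsv()` restores it losslessly (full double precision).
#'
#' @param x an `"rvhglm"` fit or its summary table.
#' @param path output file path.
#' @return `write_rvhglm_tsv` returns `path` invisibly; `read_rvhglm_tsv`
#'   returns the table.
#' @export
write_rvhglm_tsv <- function(x, path) {
  tab <- if (inherits(x, "rvhglm")) summary(x) else x
  tab <- as.data.frame(tab)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], format, digits = 17, trim = TRUE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rvhglm_tsv
#' @export
read_rvhglm_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  numcols <- setdiff(names(tab), c("term", "kind", "group"))
  tab[numcols] <- lapply(tab[numcols], as.numeric)
  tab
}
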