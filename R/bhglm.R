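# Single-stage hierarchical GLM fitted by EM-within-IWLS.
#
# Design columns are tagged by the prior they carry:
#   "intercept" - N(0, large fixed variance)
#   "coef"      - N(0, psi) with psi ~ Gamma(0.5, 0.5)  (group effects and
#                 covariates)
#   "weight"    - N(mu_j, tau_j^2), tau_j ~ half-Cauchy(0, s_k) with a
#                 group-specific scale s_k estimated from the data
#   "fixed"     - N(prior_mean, prior_variance) with both fixed (used for
#                 ridge-type fits and effectively-flat priors)
# Each EM-IWLS step replaces the unknown prior variances by their
# conditional expectations (E-step) and then takes one IWLS step on the
# normal equations augmented with one pseudo-observation per penalized
# coefficient (M-step), followed by a dispersion update for gaussian/Gamma
# models under p(phi) ~ 1/phi.

#' Control parameters for hierarchical GLM fitting
#'
#' @param tol convergence tolerance on the relative deviance change
#'   `|D_t - D_{t-1}| / (|D_t| + 0.1)`.
#' @param max_iter maximum number of EM-IWLS steps.
#' @param t_min floor for the inverse squared group scale (see
#'   [group_scale_update()]).
#' @param psi_min variance floor for group-effect/covariate priors.
#' @param intercept_variance fixed prior variance of the intercept.
#' @param s_init initial half-Cauchy group scale.
#' @param s_fixed if non-`NULL`, all group scales are frozen at this value
#'   (the fixed-scale model variant); default `NULL` estimates them.
#' @param d_floor deviation floor inside the half-Cauchy E-step (see
#'   [halfcauchy_expected_precision()]).
#' @param e_init initial expected prior precision for weight columns
#'   (1 corresponds to the starting value tau^2 = 1).
#' @param weights_fixed if `TRUE`, weight-tagged coefficients are pinned at
#'   their prior means (zero prior variance) and not estimated.
#' @param dispersion if non-`NULL`, the dispersion is held fixed at this
#'   value instead of being estimated (gaussian/Gamma only).
#' @return a named list of control values.
#' @export
bhglm_control <- function(tol = 1e-5, max_iter = 200, t_min = 1e-6,
                          psi_min = 1e-4, intercept_variance = 1e6,
                          s_init = 0.5, s_fixed = NULL, d_floor = 0.01,
                          e_init = 1, weights_fixed = FALSE,
                          dispersion = NULL) {
  if (intercept_variance < 1e4) stop("'intercept_variance' must be >= 1e4")
  list(tol = tol, max_iter = max_iter, t_min = t_min, psi_min = psi_min,
       intercept_variance = intercept_variance, s_init = s_init,
       s_fixed = s_fixed, d_floor = d_floor, e_init = e_init,
       weights_fixed = weights_fixed, dispersion = dispersion)
}

# initial state for the EM-IWLS engine
.bhglm_init <- function(y, X, family, tags, prior_mean, weight_group, control) {
  p <- ncol(X)
  coef <- numeric(p)
  names(coef) <- colnames(X)
  coef[tags == "intercept"] <- apply_link(
    switch(family$family,
           gaussian = mean(y),
           binomial = min(max(mean(y), 0.02), 0.98),
           poisson  = max(mean(y), 0.1),
           Gamma    = max(mean(y), 0.1)),
    family)
  coef[tags == "weight"] <- prior_mean[tags == "weight"]
  coef[tags == "fixed"] <- prior_mean[tags == "fixed"]
  wix <- which(tags == "weight")
  groups <- unique(weight_group[wix])
  s <- stats::setNames(rep(control$s_init, length(groups)), groups)
  if (!is.null(control$s_fixed)) s[] <- control$s_fixed
  list(coef = coef,
       lambda = stats::setNames(rep(1, length(wix)), colnames(X)[wix]),
       s = s,
       psi = stats::setNames(rep(1, sum(tags == "coef")),
                             colnames(X)[tags == "coef"]),
       phi = if (is.null(control$dispersion)) 1 else control$dispersion,
       expected_precision = stats::setNames(rep(control$e_init, length(wix)),
                                            colnames(X)[wix]),
       deviance = Inf)
}

# per-column prior precision and mean under the current state
.bhglm_prior <- function(tags, prior_mean, prior_variance, weight_group,
                         state, control) {
  p <- length(tags)
  prec <- numeric(p)
  mean_ <- prior_mean
  prec[tags == "intercept"] <- 1 / control$intercept_variance
  prec[tags == "coef"] <- 1 / state$psi
  prec[tags == "fixed"] <- 1 / prior_variance[tags == "fixed"]
  if (any(tags == "weight")) prec[tags == "weight"] <- state$expected_precision
  list(precision = prec, mean = mean_)
}

# One EM-IWLS step: an IWLS step on the prior-augmented normal equations
# using the current hyperparameter state, then the E-step updating the
# expected prior precisions, group scales and coef-prior variances from the
# new coefficients. M before E so the first step runs from the prescribed
# initialization (tau^2 = 1, psi = 1) rather than evaluating the prior
# spike at the starting values b = mu.
.bhglm_step <- function(y, X, family, tags, prior_mean, prior_variance,
                        weight_group, offset, state, control) {
  wix <- which(tags == "weight")
  gix <- which(tags == "coef")
  est <- if (control$weights_fixed) setdiff(seq_along(tags), wix) else seq_along(tags)
  if (control$weights_fixed && length(wix)) {
    state$coef[wix] <- prior_mean[wix]
    offset <- offset + drop(X[, wix, drop = FALSE] %*% prior_mean[wix])
  }
  Xe <- X[, est, drop = FALSE]
  eta <- drop(Xe %*% state$coef[est]) + offset
  wk <- .iwls_working(y, eta, offset, family, rep(1, length(y)))
  pr <- .bhglm_prior(tags, prior_mean, prior_variance, weight_group, state, control)
  prec <- pr$precision[est] * state$phi   # phi = 1 when dispersion is fixed at 1
  sw <- sqrt(wk$w)
  Xw <- Xe * sw
  A <- crossprod(Xw)
  diag(A) <- diag(A) + prec
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    r <- qr(rbind(Xw, diag(sqrt(prec), length(est))))
    bad <- colnames(Xe)[r$pivot[-seq_len(r$rank)]]
    stop("singular augmented system; offending column(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
  }
  rhs <- crossprod(Xw, wk$z * sw) + prec * pr$mean[est]
  coef_new <- drop(backsolve(ch, forwardsolve(t(ch), rhs)))
  state$coef[est] <- coef_new
  inv <- chol2inv(ch)
  dimnames(inv) <- list(colnames(Xe), colnames(Xe))

  eta <- drop(Xe %*% state$coef[est]) + offset
  mu <- family$linkinv(eta)
  if (family$family %in% c("binomial", "poisson", "Gamma"))
    mu <- pmax(mu, .Machine$double.eps)
  if (family$family == "binomial") mu <- pmin(mu, 1 - .Machine$double.eps)
  dev <- glm_deviance(y, mu, family)
  if (!is.finite(dev)) stop("non-finite deviance in EM-IWLS step")

  ## dispersion update from weighted residuals, augmented rows included
  if (!attr(family, "dispersion_fixed") && is.null(control$dispersion)) {
    wk2 <- .iwls_working(y, eta, offset, family, rep(1, length(y)))
    rss <- sum(wk2$w * (wk2$z - (eta - offset))^2) +
      sum(prec * (state$coef[est] - pr$mean[est])^2)
    state$phi <- rss / (length(y) + length(est) + 2)
  }

  ## E-step from the new coefficients (posterior curvature for coef priors)
  post_var <- stats::setNames(rep(NA_real_, length(tags)), colnames(X))
  post_var[est] <- state$phi * diag(inv)
  if (length(wix) && !control$weights_fixed) {
    # coordinate profile for each weight: unpenalized target delta_j given
    # the other coefficients, and its likelihood information i_j
    dA <- colSums(Xw^2)                       # diag of X'WX (est-indexed)
    XtWz <- rhs - prec * pr$mean[est]
    XtWXb <- drop(A %*% coef_new) - prec * coef_new
    wpos <- match(wix, est)
    i_w <- dA[wpos] / state$phi
    delta <- ifelse(dA[wpos] > 1e-12,
                    (XtWz[wpos] - XtWXb[wpos] + dA[wpos] * coef_new[wpos]) /
                      dA[wpos],
                    prior_mean[wix])
    dvn <- delta - prior_mean[wix]
    if (is.null(control$s_fixed)) {
      for (k in names(state$s)) {
        in_k <- weight_group[wix] == k
        state$s[k] <- .update_s_group_eb(dvn[in_k], 1 / i_w[in_k],
                                         control$d_floor)
      }
    }
    d_choice <- .weight_map_decisions(
      dvn, i_w, unname(state$s[as.character(weight_group[wix])]),
      control$d_floor)
    sk <- state$s[as.character(weight_group[wix])]
    e <- halfcauchy_expected_precision(d_choice, 0, sk, control$d_floor)
    state$expected_precision <- stats::setNames(e, names(state$expected_precision))
    state$lambda <- stats::setNames(1 / (1 / sk^2 + e), names(state$lambda))
  }
  if (length(gix))
    state$psi <- stats::setNames(
      .psi_em(sqrt(state$coef[gix]^2 + post_var[gix]), control$psi_min),
      names(state$psi))

  state$deviance <- dev
  list(state = state, inv = inv, eta = eta, fitted = mu, estimated = est)
}

# Wald summaries for a finished fit
.bhglm_infer <- function(state, inv, family, n, tags, est) {
  se <- rep(NA_real_, length(tags))
  se[est] <- sqrt(state$phi * diag(inv))
  p <- rep(NA_real_, length(tags))
  df <- if (attr(family, "dispersion_fixed")) Inf else max(n - length(est), 1)
  ok <- which(!is.na(se) & se > 0)
  p[ok] <- vapply(ok, function(i)
    wald_test(state$coef[i], se[i], df)$p_value, numeric(1))
  list(se = se, p = p, df = df)
}

#' Fit a hierarchical GLM by EM-within-IWLS
#'
#' Finds the posterior mode of a generalized linear model in which design
#' columns carry shrinkage priors: half-Cauchy scale-mixture priors for
#' per-variant weights (tag `"weight"`), weakly informative
#' Gamma(0.5, 0.5)-variance priors for covariate and group-effect
#' coefficients (tag `"coef"`), a diffuse normal prior for the intercept and
#' optionally fixed normal priors (tag `"fixed"`). Sample size may be
#' smaller than the number of columns; the priors regularize the fit.
#'
#' @param X numeric design matrix with column names.
#' @param y response vector.
#' @param family a family accepted by [check_family()].
#' @param tags character vector, one of `"intercept"`, `"coef"`, `"weight"`,
#'   `"fixed"` per column. Default: the first all-ones column is the
#'   intercept and every other column `"coef"`.
#' @param prior_mean per-column prior means (default 0; weight columns
#'   typically carry 1 or a functional score).
#' @param weight_group group label per column (used for `"weight"` columns;
#'   ignored elsewhere).
#' @param prior_variance per-column prior variances, used only for columns
#'   tagged `"fixed"`.
#' @param offset optional additive offset on the linear-predictor scale.
#' @param control a list from [bhglm_control()].
#' @param n_steps if non-`NULL`, run exactly this many EM-IWLS steps instead
#'   of iterating to convergence (used by the alternating multiplicative
#'   fitter).
#' @param state optional warm-start state from a previous fit.
#' @return an object of class `"bhglm"`: coefficient modes, standard errors
#'   and p-values, dispersion, hyperparameter state, deviance trace and
#'   convergence flag.
#' @examples
#' set.seed(1)
#' X <- cbind("(Intercept)" = 1, x = rnorm(80))
#' y <- drop(X %*% c(0.5, 0.3)) + rnorm(80, sd = 0.5)
#' fit <- bhglm(X, y)
#' coef(fit)
#' @export
bhglm <- function(X, y, family = stats::gaussian(), tags = NULL,
                  prior_mean = NULL, weight_group = NULL,
                  prior_variance = NULL, offset = NULL,
                  control = bhglm_control(), n_steps = NULL, state = NULL) {
  family <- check_family(family)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (n < 2) stop("need at least two observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  p <- ncol(X)
  if (is.null(tags)) {
    tags <- rep("coef", p)
    ones <- which(apply(X, 2, function(v) all(v == 1)))
    if (length(ones)) tags[ones[1]] <- "intercept"
  }
  if (length(tags) != p) stop("'tags' must have one entry per column")
  if (!all(tags %in% c("intercept", "coef", "weight", "fixed")))
    stop("invalid tag(s): ", paste(setdiff(tags, c("intercept", "coef", "weight", "fixed")), collapse = ", "))
  if (is.null(prior_mean)) prior_mean <- numeric(p)
  if (length(prior_mean) != p) stop("'prior_mean' must have one entry per column")
  if (is.null(weight_group)) weight_group <- rep(NA_character_, p)
  weight_group <- as.character(weight_group)
  if (any(tags == "weight" & is.na(weight_group)))
    stop("every 'weight' column needs a 'weight_group'")
  if (is.null(prior_variance)) prior_variance <- rep(NA_real_, p)
  if (any(tags == "fixed" & !(prior_variance > 0)))
    stop("every 'fixed' column needs a positive 'prior_variance'")
  if (is.null(offset)) offset <- rep(0, n)

  if (is.null(state)) state <- .bhglm_init(y, X, family, tags, prior_mean,
                                           weight_group, control)
  trace <- numeric(0)
  converged <- FALSE
  dev_prev <- state$deviance
  steps <- if (is.null(n_steps)) control$max_iter else n_steps
  step <- NULL
  for (it in seq_len(steps)) {
    step <- .bhglm_step(y, X, family, tags, prior_mean, prior_variance,
                        weight_group, offset, state, control)
    state <- step$state
    trace <- c(trace, state$deviance)
    if (is.null(n_steps) &&
        abs(state$deviance - dev_prev) / (abs(state$deviance) + 0.1) < control$tol) {
      converged <- TRUE
      break
    }
    dev_prev <- state$deviance
  }
  inf <- .bhglm_infer(state, step$inv, family, n, tags, step$estimated)
  structure(list(coefficients = state$coef,
                 std_errors = stats::setNames(inf$se, colnames(X)),
                 p_values = stats::setNames(inf$p, colnames(X)),
                 dispersion = state$phi,
                 hyper = state[c("lambda", "s", "psi", "expected_precision")],
                 deviance = state$deviance, deviance_trace = trace,
                 converged = converged || !is.null(n_steps),
                 n_iter = length(trace), df = inf$df,
                 family = family, tags = tags, prior_mean = prior_mean,
                 weight_group = weight_group, offset = offset,
                 fitted = step$fitted, eta = step$eta, cov_unscaled = step$inv,
                 state = state, y = y, X = X,
                 call = match.call()),
            class = "bhglm")
}

#' @export
print.bhglm <- function(x, ...) {
  cat("Hierarchical GLM (EM-IWLS posterior mode)\n")
  cat("  family:", x$family$family, "(", x$family$link, "link )\n")
  cat("  columns:", length(x$coefficients), " observations:", length(x$y), "\n")
  cat("  deviance:", format(x$deviance, digits = 6),
      " dispersion:", format(x$dispersion, digits = 4), "\n")
  cat("  steps:", x$n_iter, if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
coef.bhglm <- function(object, ...) object$coefficients

#' @export
summary.bhglm <- function(object, ...) {
  out <- data.frame(term = names(object$coefficients),
                    tag = object$tags,
                    estimate = unname(object$coefficients),
                    se = unname(object$std_errors),
                    p = unname(object$p_values),
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.bhglm", "data.frame")
  out
}

#' @export
residuals.bhglm <- function(object, type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted; fam <- object$family
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(fam$variance(mu)),
         deviance = sign(y - mu) * sqrt(pmax(fam$dev.resids(y, mu, rep(1, length(y))), 0)))
}

#' @export
predict.bhglm <- function(object, newdata = NULL, type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) object$eta
         else drop(as.matrix(newdata)[, names(object$coefficients), drop = FALSE] %*%
                   object$coefficients)
  if (type == "link") eta else object$family$linkinv(eta)
}

#' All-variants main-effect model
#'
#' The reduced model that ignores group effects and fits every variant's
#' main effect directly, each under a half-Cauchy shrinkage prior with prior
#' mean 0 and its own group scale. Useful for detecting individual variants
#' with large effects; group-level inference is by the minimum p-value over
#' a group's variants (see [group_min_pvalue()]).
#'
#' @param y response vector.
#' @param covariates numeric matrix of covariates (may be `NULL`).
#' @param genotypes numeric matrix of imputed dosages (no missing values),
#'   with variant ids as column names; monomorphic columns are an error.
#' @param family a family accepted by [check_family()].
#' @param control a list from [bhglm_control()].
#' @return a `"bhglm"` fit with one `weight` column per variant.
#' @export
fit_all_variants <- function(y, covariates = NULL, genotypes,
                             family = stats::gaussian(),
                             control = bhglm_control()) {
  genotypes <- as.matrix(genotypes)
  if (anyNA(genotypes)) stop("genotypes contain missing values; impute first")
  v <- apply(genotypes, 2, stats::var)
  if (any(v == 0))
    stop("monomorphic (zero-variance) variant column(s): ",
         paste(colnames(genotypes)[v == 0], collapse = ", "))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("variant", seq_len(ncol(genotypes)))
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  X <- cbind("(Intercept)" = rep(1, length(y)), covariates, genotypes)
  nc <- if (is.null(covariates)) 0 else ncol(covariates)
  nv <- ncol(genotypes)
  tags <- c("intercept", rep("coef", nc), rep("weight", nv))
  wgrp <- c(rep(NA_character_, 1 + nc), colnames(genotypes))
  bhglm(X, y, family, tags = tags, prior_mean = numeric(ncol(X)),
        weight_group = wgrp, control = control)
}

#' Minimum p-value over a group of variants
#'
#' Group-level assessment for the all-variants model: the unadjusted
#' minimum of the group's per-variant p-values.
#'
#' @param fit a `"bhglm"` fit (typically from [fit_all_variants()]).
#' @param group character vector of variant ids present in the fit.
#' @return the minimum p-value.
#' @export
group_min_pvalue <- function(fit, group) {
  if (!inherits(fit, "bhglm")) stop("'fit' must be a bhglm object")
  miss <- setdiff(group, names(fit$p_values))
  if (length(miss)) stop("unknown variant id(s): ", paste(miss, collapse = ", "))
  min(fit$p_values[group])
}
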