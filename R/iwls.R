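# Classical GLM machinery: IWLS, Wald inference, BH adjustment.
# This is the substrate the hierarchical fitter augments; stats::glm serves
# as the independent oracle in the test suite, never as the implementation.

# One weighted-least-squares solve: returns coefficients and the inverse
# normal-equations matrix. w are working weights, z the working response.
.wls_solve <- function(X, z, w) {
  sw <- sqrt(w)
  Xw <- X * sw
  XtWX <- crossprod(Xw)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) {
    bad <- colnames(X)[qr(Xw)$pivot[-seq_len(qr(Xw)$rank)]]
    stop("singular design; offending column(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
  }
  coef <- backsolve(ch, forwardsolve(t(ch), crossprod(Xw, z * sw)))
  inv <- chol2inv(ch)
  dimnames(inv) <- list(colnames(X), colnames(X))
  list(coef = drop(coef), inv = inv)
}

# working response and weights at the current eta
.iwls_working <- function(y, eta, offset, family, weights) {
  mu <- family$linkinv(eta)
  mu.eta <- family$mu.eta(eta)
  V <- family$variance(mu)
  w <- weights * mu.eta^2 / V
  z <- (eta - offset) + (y - mu) / mu.eta
  list(mu = mu, w = w, z = z)
}

# domain-safe starting eta
.start_eta <- function(y, family, n) {
  mubar <- switch(family$family,
                  gaussian = mean(y),
                  binomial = min(max(mean(y), 0.02), 0.98),
                  poisson  = max(mean(y), 0.1),
                  Gamma    = max(mean(y), 0.1))
  rep(family$linkfun(mubar), n)
}

#' Classical GLM fit by iteratively weighted least squares
#'
#' Maximum-likelihood fit of a generalized linear model, iterating weighted
#' least squares on the working response until the relative deviance change
#' `|D_t - D_{t-1}| / (|D_t| + 0.1)` falls below `tol`. The dispersion is
#' estimated as Pearson chi-squared over `n - p` for gaussian and Gamma
#' models and fixed at 1 for binomial and poisson.
#'
#' Non-convergence at `max_iter` is flagged in the returned object, not
#' raised, so that simulation harnesses can count such fits.
#'
#' @param y response vector.
#' @param X numeric design matrix (full column rank), including any
#'   intercept column.
#' @param family a family accepted by [check_family()].
#' @param offset optional additive offset on the linear-predictor scale.
#' @param max_iter,tol iteration controls.
#' @return list with `coefficients`, `cov` (coefficient covariance:
#'   dispersion times the inverse weighted normal-equations matrix),
#'   `std_errors`, `p_values`, `dispersion`, `deviance`, `deviance_trace`,
#'   `df_residual`, `converged`, `n_iter`, `fitted` and `eta`.
#' @examples
#' X <- cbind(1, x = rnorm(50))
#' y <- rbinom(50, 1, plogis(X %*% c(-0.5, 1)))
#' fit <- iwls_classical(y, X, binomial())
#' fit$coefficients
#' @export
iwls_classical <- function(y, X, family, offset = NULL, max_iter = 50, tol = 1e-8) {
  family <- check_family(family)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (n < p) stop("more columns than observations")
  if (is.null(offset)) offset <- rep(0, n)
  wts <- rep(1, n)

  eta <- .start_eta(y, family, n)
  dev <- glm_deviance(y, family$linkinv(eta), family)
  trace <- dev
  converged <- FALSE
  sol <- NULL
  for (it in seq_len(max_iter)) {
    wk <- .iwls_working(y, eta, offset, family, wts)
    sol <- .wls_solve(X, wk$z, wk$w)
    eta <- drop(X %*% sol$coef) + offset
    mu <- family$linkinv(eta)
    if (family$family %in% c("binomial", "poisson", "Gamma"))
      mu <- pmax(mu, .Machine$double.eps)
    if (family$family == "binomial") mu <- pmin(mu, 1 - .Machine$double.eps)
    dev_new <- glm_deviance(y, mu, family)
    trace <- c(trace, dev_new)
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  mu <- family$linkinv(eta)
  pearson <- sum((y - mu)^2 / family$variance(mu))
  dispersion <- if (attr(family, "dispersion_fixed")) 1 else pearson / (n - p)
  cov <- sol$inv * dispersion
  se <- sqrt(diag(cov))
  df <- if (attr(family, "dispersion_fixed")) Inf else n - p
  wald <- mapply(function(b, s) wald_test(b, s, df)$p_value, sol$coef, se)
  names(wald) <- colnames(X)
  cf <- sol$coef
  names(cf) <- colnames(X)
  list(coefficients = cf, cov = cov, std_errors = stats::setNames(se, colnames(X)),
       p_values = wald, dispersion = dispersion, deviance = dev,
       deviance_trace = trace, df_residual = n - p,
       converged = converged, n_iter = it, fitted = mu, eta = eta)
}

#' Two-sided Wald test
#'
#' @param estimate coefficient estimate.
#' @param std_error its standard error (must be positive).
#' @param df reference degrees of freedom: `Inf` for a standard-normal
#'   reference (binomial/poisson), finite for a t reference (gaussian/Gamma
#'   with estimated dispersion).
#' @return list with `estimate`, `std_error`, `z_or_t` and two-sided
#'   `p_value`.
#' @examples
#' wald_test(2, 1, 10)$p_value  # 0.0734
#' @export
wald_test <- function(estimate, std_error, df = Inf) {
  if (!is.finite(std_error) || std_error <= 0) stop("'std_error' must be positive and finite")
  stat <- estimate / std_error
  p <- if (is.infinite(df)) 2 * stats::pnorm(-abs(stat)) else 2 * stats::pt(-abs(stat), df)
  list(estimate = estimate, std_error = std_error, z_or_t = stat, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values,
#' returned in the input order.
#'
#' @param p_values numeric vector with values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
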