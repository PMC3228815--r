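#' Validate and normalise a GLM family
#'
#' The modelling functions in this package accept the usual [stats::family]
#' objects (or the family name as a string). Four exponential-family
#' distributions are supported: gaussian, binomial, poisson and Gamma, with
#' the identity, logit, log and inverse links. The dispersion parameter is
#' fixed at 1 for binomial and poisson models and estimated from the data
#' otherwise.
#'
#' @param family a [stats::family] object, a family function (e.g.
#'   `binomial`), or a character name.
#' @return the validated `family` object, with an added logical attribute
#'   `dispersion_fixed`.
#' @examples
#' fam <- check_family(binomial())
#' attr(fam, "dispersion_fixed")
#' @export
check_family <- function(family) {
  if (is.character(family)) family <- get(family, mode = "function", envir = parent.frame())
  if (is.function(family)) family <- family()
  if (!inherits(family, "family")) stop("'family' must be a stats::family object")
  ok <- c("gaussian", "binomial", "poisson", "Gamma")
  if (!family$family %in% ok)
    stop("unsupported family '", family$family, "'; supported: ",
         paste(ok, collapse = ", "))
  links <- c("identity", "logit", "log", "inverse")
  if (!family$link %in% links)
    stop("unsupported link '", family$link, "'; supported: ",
         paste(links, collapse = ", "))
  attr(family, "dispersion_fixed") <- family$family %in% c("binomial", "poisson")
  family
}

# open mean-domain check for a family's link
.mu_valid <- function(mu, family) {
  switch(family$family,
         gaussian = rep(TRUE, length(mu)),
         binomial = mu > 0 & mu < 1,
         poisson  = mu > 0,
         Gamma    = mu > 0)
}

#' Apply a family's link function
#'
#' Maps a mean value to the linear-predictor scale, `eta = h(mu)`. Values
#' outside the open domain of the link (for example 0 or 1 under the logit
#' link) raise an error rather than returning an infinity.
#'
#' @param mu numeric vector of means, inside the open mean domain.
#' @param family a family accepted by [check_family()].
#' @return numeric vector `eta` with `inv_link(apply_link(mu)) == mu`.
#' @examples
#' apply_link(0.5, binomial())  # 0
#' @export
apply_link <- function(mu, family) {
  family <- check_family(family)
  if (!all(.mu_valid(mu, family)))
    stop("mean value outside the open domain of the ", family$link, " link")
  family$linkfun(mu)
}

#' Invert a family's link function
#'
#' @param eta numeric vector on the linear-predictor scale.
#' @inheritParams apply_link
#' @return numeric vector of means.
#' @export
inv_link <- function(eta, family) {
  family <- check_family(family)
  family$linkinv(eta)
}

#' GLM deviance
#'
#' Computes the family deviance `sum(dev.resids(y, mu, 1))`, the quantity
#' monitored by the fitting algorithms' convergence criterion. It is zero at
#' the saturated fit.
#'
#' @param y response vector.
#' @param mu fitted mean vector, same length as `y`, inside the valid mean
#'   domain.
#' @inheritParams apply_link
#' @param weights optional prior observation weights (binomial totals etc.);
#'   default 1.
#' @return non-negative scalar deviance.
#' @examples
#' glm_deviance(c(0, 2), c(1, 1), gaussian())  # 2
#' @export
glm_deviance <- function(y, mu, family, weights = NULL) {
  family <- check_family(family)
  if (length(y) != length(mu)) stop("'y' and 'mu' must have the same length")
  if (!all(.mu_valid(mu, family) | (family$family == "binomial" & (mu == 0 | mu == 1) & y == mu)))
    stop("'mu' outside the valid mean domain for family ", family$family)
  if (is.null(weights)) weights <- rep(1, length(y))
  sum(family$dev.resids(y, mu, weights))
}
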