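# Shared fixture builders; everything is generated in code at test time.

# small grouped-variant dataset with known effects
make_grouped_sim <- function(n = 400, J = c(4, 4), mafs = NULL,
                             beta = NULL, sigma_e = 0.2, seed = 1,
                             family = "gaussian") {
  set.seed(seed)
  K <- length(J)
  if (is.null(mafs)) mafs <- rep(0.15, sum(J))
  ids <- paste0("v", seq_len(sum(J)))
  z <- vapply(mafs, function(q) rbinom(n, 2, q), numeric(n))
  colnames(z) <- ids
  groups <- split(ids, rep(paste0("G", seq_len(K)), J))[paste0("G", seq_len(K))]
  if (is.null(beta)) beta <- rep(0, sum(J))
  eta <- drop(z %*% beta)
  y <- if (family == "binomial") rbinom(n, 1, plogis(eta - mean(eta)))
       else eta + rnorm(n, 0, sigma_e)
  covariates <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  list(y = y + if (family == "gaussian") 0.3 * covariates[, "x1"] else 0,
       z = z, groups = groups, beta = beta, covariates = covariates)
}

# random design for GLM oracle sweeps
make_glm_problem <- function(n = 100, p = 3, family, seed = 1) {
  set.seed(seed)
  X <- cbind("(Intercept)" = 1, matrix(rnorm(n * (p - 1)), n,
                                       dimnames = list(NULL, paste0("x", seq_len(p - 1)))))
  beta <- c(0.4, runif(p - 1, -0.5, 0.5))
  eta <- drop(X %*% beta)
  y <- switch(family$family,
              gaussian = eta + rnorm(n, 0, 0.7),
              binomial = rbinom(n, 1, family$linkinv(eta)),
              poisson  = rpois(n, exp(eta)),
              Gamma    = rgamma(n, shape = 4, scale = exp(eta) / 4))
  list(X = X, y = y, beta = beta)
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    prev <- min(prev, m / r * p[o[r]])
    adj[o[r]] <- prev
  }
  adj
}
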