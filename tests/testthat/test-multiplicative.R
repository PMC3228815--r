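test_that("genetic scores are weighted burden sums", {
  z <- cbind(v1 = c(0, 1, 2), v2 = c(1, 0, 0), v3 = c(2, 2, 0))
  b <- c(v1 = 1, v2 = 1, v3 = 1)
  expect_equal(genetic_score(z, b, c("v1", "v2")), rowSums(z[, 1:2]))
  expect_equal(genetic_score(z, b * 0, colnames(z)), rep(0, 3))
  expect_equal(genetic_score(z, 2 * b, colnames(z)),
               2 * genetic_score(z, b, colnames(z)))
  expect_error(genetic_score(z, b, "v9"), "unknown")
})

test_that("adjusted effects use the stated delta-method standard error", {
  a <- adjusted_effects(g = 0.3, g_se = 0.1, b = 1.4, b_se = 0.2, mu = 1)
  expect_equal(a$estimate, 0.3 * 0.4)
  expect_equal(a$se, sqrt(0.3^2 * 0.2^2 + 0.4^2 * 0.1^2), tolerance = 1e-12)
  expect_equal(a$se, 0.0721, tolerance = 1e-3)
  # Monte-Carlo error propagation cross-check (small SEs so the
  # first-order delta approximation is accurate)
  a2 <- adjusted_effects(g = 0.3, g_se = 0.01, b = 1.4, b_se = 0.02, mu = 1)
  set.seed(1)
  gs <- rnorm(2e5, 0.3, 0.01); bs <- rnorm(2e5, 1.4, 0.02)
  expect_equal(sd(gs * (bs - 1)), a2$se, tolerance = 0.02)

  expect_equal(adjusted_effects(0, 0.1, 1.4, 0.2, 1)$estimate, 0)
  edge <- adjusted_effects(0, 0, 1, 0, 1)     # no deviation, no variance
  expect_equal(edge$p, 1)
  expect_error(adjusted_effects(0.3, NA, 1.4, 0.2, 1), "missing")
})

test_that("fixed-weight multiplicative model is exactly the burden-score hierarchical GLM", {
  sim <- make_grouped_sim(n = 300, J = c(3, 3), beta = rep(0.15, 6), seed = 41)
  fit <- rvhglm(sim$y, sim$covariates, sim$z, sim$groups,
                scale_mode = "weights_fixed")
  S <- cbind(G1 = rowSums(sim$z[, sim$groups$G1]),
             G2 = rowSums(sim$z[, sim$groups$G2]))
  ref <- bhglm(cbind("(Intercept)" = 1, sim$covariates, S), sim$y,
               tags = c("intercept", rep("coef", 4)))
  expect_equal(unname(fit$group_effects), unname(ref$coefficients[c("G1", "G2")]),
               tolerance = 1e-12)
  expect_equal(unname(fit$group_se), unname(ref$std_errors[c("G1", "G2")]),
               tolerance = 1e-12)
  expect_equal(unname(fit$group_p), unname(ref$p_values[c("G1", "G2")]),
               tolerance = 1e-12)
  expect_equal(unname(fit$weights), rep(1, 6))
})

test_that("forcing the estimated scale to 0.5 reproduces the fixed-scale variant", {
  sim <- make_grouped_sim(n = 400, J = c(4, 4),
                          beta = c(0.4, -0.3, 0, 0, rep(0, 4)), seed = 55)
  f_fixed <- rvhglm(sim$y, sim$covariates, sim$z, sim$groups,
                    scale_mode = "fixed", fixed_scale = 0.5)
  f_forced <- rvhglm(sim$y, sim$covariates, sim$z, sim$groups,
                     scale_mode = "estimated",
                     control = bhglm_control(s_fixed = 0.5))
  expect_lt(max(abs(f_fixed$weights - f_forced$weights)), 1e-6)
  expect_lt(max(abs(f_fixed$group_effects - f_forced$group_effects)), 1e-6)
})

test_that("the multiplicative decomposition identity holds after fitting", {
  sim <- make_grouped_sim(n = 400, J = c(4, 4),
                          beta = c(0.5, -0.4, 0.3, 0, rep(0, 4)), seed = 19)
  for (mode in c("estimated", "fixed", "weights_fixed")) {
    fit <- rvhglm(sim$y, sim$covariates, sim$z, sim$groups, scale_mode = mode)
    expect_lt(fit$eq6_max_dev, 1e-8)
  }
})

test_that("strong opposite effects yield opposite estimated weights", {
  set.seed(23)
  n <- 1500
  z <- matrix(rbinom(n * 6, 2, 0.2), n, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  beta <- c(0.4, 0.4, 0.4, -0.4, -0.4, 0)
  y <- drop(z %*% beta) + rnorm(n, 0, 0.3)
  fit <- rvhglm(y, genotypes = z, groups = list(G1 = colnames(z)))
  w <- fit$weights
  expect_gt(min(w[1:3]), 0)
  expect_lt(max(w[4:5]), 0)
  expect_lt(fit$group_p[["G1"]], 0.01)
})

test_that("result table has the documented layout and BH column", {
  sim <- make_grouped_sim(n = 250, J = c(3, 3, 3), beta = rep(0, 9), seed = 2)
  fit <- rvhglm(sim$y, sim$covariates, sim$z, sim$groups)
  tab <- summary(fit)
  expect_equal(sum(tab$kind == "group_effect"), 3)
  ge <- tab[tab$kind == "group_effect", ]
  expect_equal(ge$p_bh, unname(bh_adjust(fit$group_p)), tolerance = 1e-12)
  expect_true(all(ge$p_bh >= ge$p - 1e-12))
  fin <- is.finite(tab$se)
  expect_equal(tab$upper2se[fin] - tab$estimate[fin],
               tab$estimate[fin] - tab$lower2se[fin], tolerance = 1e-10)
  expect_equal(unique(tab$kind),
               c("intercept", "covariate", "group_effect", "weight",
                 "adjusted_effect"))
  # variants appear grouped by their group, after the group effects
  wrows <- tab[tab$kind == "weight", ]
  expect_equal(wrows$group, rep(c("G1", "G2", "G3"), each = 3))
})

test_that("result tables round-trip losslessly through TSV", {
  sim <- make_grouped_sim(n = 200, J = c(3, 3), beta = rep(0.1, 6), seed = 9)
  fit <- rvhglm(sim$y, sim$covariates, sim$z, sim$groups)
  tab <- summary(fit)
  tf <- tempfile(fileext = ".tsv")
  write_rvhglm_tsv(fit, tf)
  back <- read_rvhglm_tsv(tf)
  for (cc in c("estimate", "se", "lower2se", "upper2se", "p", "p_bh",
               "total_effect")) {
    expect_equal(back[[cc]], tab[[cc]], tolerance = 1e-15)
  }
  expect_identical(back$term, tab$term)
})

test_that("invalid group structures are rejected with guidance", {
  sim <- make_grouped_sim(n = 100, J = c(3), beta = rep(0, 3), seed = 1)
  expect_error(rvhglm(sim$y, genotypes = sim$z, groups = list()),
               "fit_all_variants")
  expect_error(rvhglm(sim$y, genotypes = sim$z,
                      groups = list(G1 = "v1", G2 = c("v2", "v3"))),
               "fewer than 2.*covariates")
  expect_error(rvhglm(sim$y, genotypes = sim$z,
                      groups = list(G1 = c("v1", "zz"))), "unknown")
  expect_error(rvhglm(sim$y, genotypes = sim$z,
                      groups = list(G1 = c("v1", "v2"), G2 = c("v2", "v3"))),
               "more than one group")
})

test_that("fits are invariant to group order and individual order", {
  sim <- make_grouped_sim(n = 300, J = c(3, 3), beta = c(0.3, 0.3, 0, 0, 0, 0),
                          seed = 31)
  f1 <- rvhglm(sim$y, sim$covariates, sim$z, sim$groups)
  f2 <- rvhglm(sim$y, sim$covariates, sim$z, rev(sim$groups))
  expect_equal(f1$group_effects[c("G1", "G2")], f2$group_effects[c("G1", "G2")],
               tolerance = 1e-8)
  perm <- sample(length(sim$y))
  f3 <- rvhglm(sim$y[perm], sim$covariates[perm, ], sim$z[perm, ], sim$groups)
  expect_equal(f1$group_effects, f3$group_effects, tolerance = 1e-8)
  expect_equal(f1$weights, f3$weights, tolerance = 1e-8)
})

test_that("groups without genetic variation get a null effect and a warning", {
  set.seed(8)
  z <- cbind(v1 = rbinom(120, 2, 0.3), v2 = rbinom(120, 2, 0.3),
             v3 = rep(0, 120), v4 = rep(0, 120))
  y <- rnorm(120)
  expect_warning(
    fit <- rvhglm(y, genotypes = z,
                  groups = list(G1 = c("v1", "v2"), G2 = c("v3", "v4"))),
    "constant genetic score")
  expect_equal(fit$group_effects[["G2"]], 0)
  expect_equal(fit$group_se[["G2"]], Inf)
  expect_equal(fit$group_p[["G2"]], 1)
})

test_that("formula interface and matrix interface agree", {
  sim <- make_grouped_sim(n = 200, J = c(3, 3), beta = rep(0.1, 6), seed = 77)
  df <- data.frame(y = sim$y, x1 = sim$covariates[, "x1"],
                   x2 = sim$covariates[, "x2"])
  f1 <- rvhglm(y ~ x1 + x2, data = df, genotypes = sim$z, groups = sim$groups)
  f2 <- rvhglm(sim$y, sim$covariates, sim$z, sim$groups)
  expect_equal(unname(f1$group_effects), unname(f2$group_effects),
               tolerance = 1e-10)
})

test_that("multiplicative S3 methods are coherent", {
  sim <- make_grouped_sim(n = 200, J = c(3, 3), beta = rep(0.2, 6), seed = 13)
  fit <- rvhglm(sim$y, sim$covariates, sim$z, sim$groups)
  expect_output(print(fit), "Group effects")
  expect_length(coef(fit, "groups"), 2)
  expect_length(coef(fit, "weights"), 6)
  expect_equal(length(fitted(fit)), 200)
  expect_equal(residuals(fit, "response"), sim$y - fitted(fit))
  pr <- predict(fit, newdata = list(covariates = sim$covariates,
                                    genotypes = sim$z))
  expect_equal(pr, fit$eta, tolerance = 1e-10)
  s1 <- simulate(fit, nsim = 2, seed = 4)
  s2 <- simulate(fit, nsim = 2, seed = 4)
  expect_identical(s1, s2)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
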