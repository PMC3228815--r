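test_that("genotype simulation follows Hardy-Weinberg proportions deterministically", {
  g1 <- simulate_genotypes(50, c(a = 0.2, b = 0.05), seed = 3)
  g2 <- simulate_genotypes(50, c(a = 0.2, b = 0.05), seed = 3)
  expect_identical(g1$dosage, g2$dosage)

  g <- simulate_genotypes(1e4, c(v = 0.5), seed = 1)
  expect_equal(mean(g$dosage), 1, tolerance = 0.02)

  g <- simulate_genotypes(1e5, c(v = 0.3), seed = 2)
  freq <- table(g$dosage) / 1e5
  expect_lt(abs(freq[["0"]] - 0.49), 0.005)
  expect_lt(abs(freq[["1"]] - 0.42), 0.005)
  expect_lt(abs(freq[["2"]] - 0.09), 0.005)

  expect_error(simulate_genotypes(10, c(0.2, 0.7)), "0, 0.5")
})

test_that("the MAF spectrum mixes uniform common and log-uniform rare frequencies", {
  m <- maf_spectrum(20, 0, seed = 5)
  expect_true(all(m >= 0.01))
  m2 <- maf_spectrum(10, 5000, n_target = 3000, seed = 6)
  expect_true(all(m2 > 0 & m2 <= 0.5))
  rare <- m2[-(1:10)]
  expect_true(all(rare < 0.01 & rare >= 1 / 6000))
  # log-uniform median: sqrt(lo * hi)
  expect_equal(median(rare), sqrt(0.01 / 6000), tolerance = 0.1)
  expect_lt(median(rare), 0.005)
})

test_that("the heritability-calibrated effect bound has the stated algebra", {
  expect_equal(compute_beta_h(0, runif(5, 0.01, 0.4)), 0)
  q <- c(0.1, 0.2, 0.05)
  b1 <- compute_beta_h(0.01, q, sigma_e = 0.2)
  # doubling every 2q(1-q) term scales beta_h by 1/sqrt(2); emulate by
  # duplicating the variant set
  b2 <- compute_beta_h(0.01, c(q, q), sigma_e = 0.2)
  expect_equal(b2, b1 / sqrt(2), tolerance = 1e-12)
  expect_true(compute_beta_h(0.02, q) > compute_beta_h(0.01, q))
  expect_error(compute_beta_h(1, q), "0, 1")
})

test_that("simulated group variance fractions recover the target heritability", {
  set.seed(10)
  h <- 0.007; J <- 20; n <- 1000; sigma_e <- 0.2
  realized <- replicate(80, {
    q <- maf_spectrum(4, J - 4, n_target = n)
    z <- simulate_genotypes(n, q)$dosage
    beta <- simulate_effects(J, compute_beta_h(h, q, sigma_e), p_neg = 0)
    gp <- drop(z %*% beta)
    y <- gp + rnorm(n, 0, sigma_e)
    var(gp) / var(y)
  })
  expect_lt(abs(mean(realized) - h), 0.0015)
})

test_that("effect sampling respects the sign-flip probability", {
  expect_true(all(simulate_effects(100, 0.5, p_neg = 0, seed = 1) >= 0))
  expect_equal(simulate_effects(10, 0, 0.4, seed = 2), rep(0, 10))
  set.seed(3)
  b <- simulate_effects(1e5, 1, p_neg = 0.4)
  expect_equal(mean(b < 0), 0.4, tolerance = 0.005)
  expect_true(all(abs(b) <= 1))
  expect_error(simulate_effects(10, 1, p_neg = 1.5), "0, 1")
})

test_that("phenotype simulation matches the residual SD and the median split", {
  set.seed(4)
  z <- simulate_genotypes(1e4, c(v1 = 0.2, v2 = 0.1))
  ph <- simulate_phenotype(z, 0, c(0, 0), "continuous", sigma_e = 0.2)
  expect_equal(sd(ph$y), 0.2, tolerance = 0.01)

  phb <- simulate_phenotype(z, 0, c(0, 0), "binary", sigma_e = 0.2)
  expect_equal(mean(phb$y), 0.5)

  p1 <- simulate_phenotype(z, 0, c(0.1, 0), "continuous", seed = 9)
  p2 <- simulate_phenotype(z, 0, c(0.1, 0), "continuous", seed = 9)
  expect_identical(p1$y, p2$y)
  expect_error(simulate_phenotype(z, 0, c(0, 0), sigma_e = -1), "positive")
})

test_that("the scenario catalog reproduces the study design tables", {
  sc <- scenario_catalog("three_groups", "a", 3008)
  expect_equal(sc$J, c(10, 26, 44))
  expect_equal(sc$h, c(0, 0.005, 0))
  expect_equal(sc$p_neg[2], 0)

  sc <- scenario_catalog("three_groups", "d", 1499)
  expect_equal(sc$J, c(11, 16, 34))
  expect_equal(sc$h, c(0.007, 0.007, 0))
  expect_equal(sc$p_neg[1:2], c(0.4, 0.4))

  sc <- scenario_catalog("six_groups", "b", 3008)
  expect_equal(sc$J, c(5, 5, 13, 13, 22, 22))
  expect_equal(which(sc$h > 0), c(2, 5))
  expect_equal(sc$h[c(2, 5)], c(0.007, 0.007))
  expect_equal(sc$p_neg[c(2, 5)], c(0.4, 0.4))

  sc <- scenario_catalog("six_groups", "c", 1499)
  expect_equal(sc$J, c(5, 6, 8, 8, 17, 17))

  expect_equal(scenario_catalog("three_groups", "f", 3008)$h, c(0, 0.007, 0.007))
  expect_error(scenario_catalog("three_groups", "z"), "unknown scenario")
  expect_error(scenario_catalog("six_groups", "e"), "unknown scenario")
  expect_error(scenario_catalog("three_groups", "a", n = 500), "3008 or 1499")
})

test_that("scenario datasets have the full structure and are reproducible", {
  sc <- scenario_catalog("three_groups", "a", 3008)
  ds <- simulate_scenario(sc, "continuous", seed = 77)
  expect_equal(ncol(ds$genotypes$dosage), 80)
  expect_equal(vapply(ds$groups, length, 1L),
               c(G1 = 10L, G2 = 26L, G3 = 44L))
  expect_equal(ncol(ds$singletons), 2)
  expect_equal(nrow(ds$pheno), 3008)
  expect_true(all(c("sample_id", "y", "race", "age", "sex", "bmi") %in%
                    names(ds$pheno)))
  expect_equal(length(ds$beta_true), 80)
  # null groups carry exactly zero effects; the causal group does not
  expect_true(all(ds$beta_true[ds$groups$G1] == 0))
  expect_true(any(ds$beta_true[ds$groups$G2] != 0))

  ds2 <- simulate_scenario(sc, "continuous", seed = 77)
  expect_identical(ds$pheno$y, ds2$pheno$y)
  expect_identical(ds$genotypes$dosage, ds2$genotypes$dosage)

  db <- simulate_scenario(sc, "binary", seed = 5)
  expect_equal(mean(db$pheno$y), 0.5)
})

test_that("dataset export writes the four TSV files consistently", {
  sc <- scenario_catalog("three_groups", "a", 1499)
  ds <- simulate_scenario(sc, "binary", seed = 11)
  dir <- tempfile()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("genotypes.tsv", "phenotype.tsv", "groups.tsv", "true_effects.tsv")))))
  g <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_equal(g$dosage, ds$genotypes$dosage)
  gm <- read_groups(file.path(dir, "groups.tsv"))
  expect_equal(nrow(gm), 61)   # 11 + 16 + 34
})
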