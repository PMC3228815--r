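write_tsv_geno <- function(m, path) {
  tab <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

test_that("genotype TSV files round-trip losslessly", {
  set.seed(1)
  m <- matrix(rbinom(30, 2, 0.3), 10, 3,
              dimnames = list(paste0("s", 1:10), c("v1", "v2", "v3")))
  m[2, 1] <- NA
  tf <- tempfile(fileext = ".tsv")
  write_tsv_geno(m, tf)
  g <- read_genotypes(tf, "tsv")
  expect_equal(g$dosage, m)
  tf2 <- tempfile(fileext = ".tsv")
  write_genotypes(g, tf2)
  g2 <- read_genotypes(tf2, "tsv")
  expect_equal(g2$dosage, g$dosage)
  expect_error(read_genotypes(tempfile(), "tsv"), "not found")
})

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3")

test_that("VCF genotypes become additive minor-allele dosages", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header,
               "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
               "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1\t0/0",
               "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1"), tf)
  g <- suppressMessages(read_genotypes(tf, "vcf"))
  expect_equal(unname(g$dosage[, "rs1"]), c(0, 1, 2))
  expect_true(is.na(g$dosage["s1", "rs2"]))
  expect_equal(unname(g$dosage[, "rs2"])[2:3], c(1, 0))
  # rs3: ALT frequency 5/6 > 0.5, so REF is the minor allele -> flipped
  expect_equal(unname(g$dosage[, "rs3"]), c(0, 0, 1))
  expect_true(all(g$maf <= 0.5))
})

test_that("multiallelic VCF records are rejected by id", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header,
               "1\t100\trs9\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"), tf)
  expect_error(read_genotypes(tf, "vcf"), "rs9")
})

test_that("mean imputation preserves observed entries and column means", {
  m <- cbind(v1 = c(0, 1, NA), v2 = c(2, 0, 1))
  rownames(m) <- paste0("s", 1:3)
  g <- read_genotypes_obj <- structure(
    list(dosage = m, maf = rvhglm:::.compute_maf(m),
         group = c(NA, NA), mu = c(NA, NA), imputed = FALSE),
    class = "geno_matrix")
  gi <- impute_mean(g)
  expect_equal(unname(gi$dosage[, "v1"]), c(0, 1, 0.5))
  expect_equal(unname(gi$dosage[, "v2"]), c(2, 0, 1))
  expect_equal(colMeans(gi$dosage), colMeans(m, na.rm = TRUE),
               tolerance = 1e-12)
  expect_equal(impute_mean(gi)$dosage, gi$dosage)
  g$dosage[, 1] <- NA
  expect_error(impute_mean(g), "v1")
})

test_that("MAF classification uses a strict 1% boundary", {
  make_g <- function(mafs) {
    n <- 4000
    set.seed(2)
    m <- vapply(mafs, function(q) rbinom(n, 2, q), numeric(n))
    colnames(m) <- paste0("v", seq_along(mafs))
    structure(list(dosage = m, maf = mafs, group = NA, mu = NA,
                   imputed = TRUE), class = "geno_matrix")
  }
  g <- make_g(c(v1 = 0.009, v2 = 0.01, v3 = 0.3))
  lab <- classify_by_maf(g)
  expect_equal(unname(lab), c("rare", "common", "common"))
  expect_true(all(lab %in% c("common", "rare")))
})

test_that("non-segregating variants are dropped and counted", {
  m <- cbind(v1 = c(0, 0, 0), v2 = c(0, 1, 0), v3 = c(2, 2, 2))
  rownames(m) <- paste0("s", 1:3)
  g <- structure(list(dosage = m, maf = rvhglm:::.compute_maf(m),
                      group = rep(NA, 3), mu = rep(NA, 3), imputed = TRUE),
                 class = "geno_matrix")
  expect_message(g2 <- drop_non_segregating(g), "2 non-segregating")
  expect_equal(colnames(g2$dosage), "v2")
  zero_var <- sum(apply(m, 2, var) == 0)
  expect_equal(ncol(m) - ncol(g2$dosage), zero_var)
})

test_that("phenotype reading drops incomplete rows and tracks the response", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ty\tage\tsex",
               "s1\t1.2\t40\t0", "s2\t0.8\tNA\t1", "s3\t1.5\t55\t1"), tf)
  expect_message(ph <- read_phenotypes(tf), "1 row")
  expect_equal(nrow(ph), 2)
  expect_equal(attr(ph, "response"), "y")
  expect_error(read_phenotypes(tf, response = "bmi"), "not found")
})

test_that("model frames join by id, expand factors and route singletons", {
  set.seed(6)
  n <- 60
  m <- vapply(c(0.3, 0.25, 0.2, 0.35), function(q) rbinom(n, 2, q), numeric(n))
  colnames(m) <- paste0("v", 1:4)
  rownames(m) <- paste0("s", seq_len(n))
  g <- structure(list(dosage = m, maf = rvhglm:::.compute_maf(m),
                      group = rep(NA, 4), mu = rep(NA, 4), imputed = TRUE),
                 class = "geno_matrix")
  pheno <- data.frame(sample_id = rownames(m), y = rnorm(n),
                      race = sample(c("b", "a", "c"), n, TRUE),
                      age = runif(n, 20, 60))
  groups <- data.frame(variant_id = c("v1", "v2", "v3"),
                       group = c("G1", "G1", "solo"))
  mf <- suppressMessages(
    build_model_frame(g, pheno, groups, unassigned = "drop"))
  expect_equal(sum(grepl("^race", colnames(mf$covariates))), 2)  # 3 levels
  expect_true("v3" %in% colnames(mf$covariates))                 # singleton
  expect_false("v4" %in% colnames(mf$covariates))                # dropped
  expect_equal(colnames(mf$genotypes), c("v1", "v2"))

  mf2 <- suppressMessages(
    build_model_frame(g, pheno, groups, unassigned = "covariate"))
  expect_true("v4" %in% colnames(mf2$covariates))

  # strict join errors on mismatch, intersect subsets
  pheno_bad <- pheno
  pheno_bad$sample_id[1] <- "sX"
  expect_error(build_model_frame(g, pheno_bad, groups), "sample ids differ")
  mf3 <- suppressMessages(
    build_model_frame(g, pheno_bad, groups, join = "intersect"))
  expect_equal(length(mf3$y), n - 1)
})

test_that("permuting phenotype rows leaves fitted coefficients unchanged", {
  set.seed(14)
  n <- 120
  m <- vapply(rep(0.3, 4), function(q) rbinom(n, 2, q), numeric(n))
  colnames(m) <- paste0("v", 1:4)
  rownames(m) <- paste0("s", seq_len(n))
  g <- structure(list(dosage = m, maf = rvhglm:::.compute_maf(m),
                      group = rep(NA, 4), mu = rep(NA, 4), imputed = TRUE),
                 class = "geno_matrix")
  pheno <- data.frame(sample_id = rownames(m),
                      y = rnorm(n) + 0.3 * m[, 1], age = runif(n))
  groups <- data.frame(variant_id = colnames(m), group = rep(c("G1", "G2"), 2))
  mf1 <- build_model_frame(g, pheno, groups)
  mf2 <- build_model_frame(g, pheno[sample(n), ], groups)
  f1 <- rvhglm(mf1$y, mf1$covariates, mf1$genotypes, mf1$groups)
  f2 <- rvhglm(mf2$y, mf2$covariates, mf2$genotypes, mf2$groups)
  expect_equal(f1$group_effects, f2$group_effects, tolerance = 1e-8)
})
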