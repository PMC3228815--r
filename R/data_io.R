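# Genotype / phenotype input handling.
#
# A geno_matrix is a light container: an individuals x variants dosage
# matrix (0/1/2 minor-allele counts, NA = missing, reals after imputation)
# plus per-variant metadata (MAF from observed entries, group label, prior
# weight mean). Sample alignment with phenotypes is by explicit id join,
# never positional.

.new_geno_matrix <- function(dosage, group = NULL, mu = NULL, imputed = FALSE) {
  J <- ncol(dosage)
  structure(list(dosage = dosage,
                 maf = .compute_maf(dosage),
                 group = if (is.null(group)) rep(NA_character_, J) else group,
                 mu = if (is.null(mu)) rep(NA_real_, J) else mu,
                 imputed = imputed),
            class = "geno_matrix")
}

# MAF from observed entries only, folded to [0, 0.5]
.compute_maf <- function(dosage) {
  f <- colMeans(dosage, na.rm = TRUE) / 2
  stats::setNames(pmin(f, 1 - f), colnames(dosage))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "variants;", sum(is.na(x$dosage)), "missing entries",
      if (x$imputed) "(imputed)" else "", "\n")
  cat("  MAF range:", paste(signif(range(x$maf), 3), collapse = " - "), "\n")
  if (!all(is.na(x$group)))
    cat("  groups:", paste(names(table(x$group)), table(x$group),
                           sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Read a genotype matrix
#'
#' TSV layout: header row of variant ids, first column `sample_id`, cells
#' in `{0, 1, 2, NA}` (or imputed reals). VCF: standard VCF 4.x with GT
#' calls at biallelic sites; the additive dosage counts the minor allele,
#' determined per variant from the observed allele frequency (ties count
#' the ALT allele as minor).
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return a `geno_matrix` object.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "sample_id") stop("first TSV column must be 'sample_id'")
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (anyDuplicated(colnames(m)))
      stop("duplicate variant id(s): ",
           paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
    if (any(m < 0 | m > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
    return(.new_geno_matrix(m, imputed = !anyNA(m)))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop("non-biallelic VCF record(s): ",
         paste(fix[multi, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  if (anyDuplicated(ids))
    stop("duplicate variant id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  alt_count <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]))
  }
  m <- t(apply(gt, 1, function(r) vapply(r, alt_count, numeric(1))))
  # orient each variant to count the minor allele (ties: ALT is minor)
  altf <- rowMeans(m, na.rm = TRUE) / 2
  flip <- !is.na(altf) & altf > 0.5
  if (any(flip))
    message("REF allele is minor for ", sum(flip), " variant(s); dosages flipped")
  m[flip, ] <- 2 - m[flip, ]
  m <- t(m)
  colnames(m) <- ids
  .new_geno_matrix(m, imputed = !anyNA(m))
}

#' Write a genotype matrix as TSV
#'
#' @param g a `geno_matrix`.
#' @param path output path.
#' @export
write_genotypes <- function(g, path) {
  m <- g$dosage
  tab <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean-impute missing genotypes
#'
#' Each missing entry is replaced by the mean of its variant's observed
#' dosages, leaving observed entries and per-variant column means unchanged.
#'
#' @param g a `geno_matrix`.
#' @return the imputed `geno_matrix`.
#' @export
impute_mean <- function(g) {
  m <- g$dosage
  allmiss <- colSums(!is.na(m)) == 0
  if (any(allmiss))
    stop("variant(s) with no observed genotypes: ",
         paste(colnames(m)[allmiss], collapse = ", "))
  if (anyNA(m)) {
    cm <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- cm[idx[, 2]]
  }
  out <- g
  out$dosage <- m
  out$imputed <- TRUE
  out
}

#' Classify variants as common or rare by MAF
#'
#' Rare iff the observed minor allele frequency is strictly below
#' `threshold` (default 1\%); the boundary value counts as common.
#'
#' @param g a `geno_matrix`.
#' @param threshold MAF threshold.
#' @return character vector `"common"`/`"rare"`, named by variant id; also
#'   attached to the object when assigned back.
#' @export
classify_by_maf <- function(g, threshold = 0.01) {
  ifelse(g$maf < threshold, "rare", "common")
}

#' Drop non-segregating variants
#'
#' Removes variants whose observed dosages have zero variance (monomorphic
#' in the sample); the removed ids are reported via [message()].
#'
#' @param g a `geno_matrix`.
#' @return the filtered `geno_matrix`.
#' @export
drop_non_segregating <- function(g) {
  v <- apply(g$dosage, 2, stats::var, na.rm = TRUE)
  dead <- !is.finite(v) | v == 0
  if (any(dead))
    message("removing ", sum(dead), " non-segregating variant(s): ",
            paste(utils::head(colnames(g$dosage)[dead], 10), collapse = ", "))
  keep <- which(!dead)
  out <- g
  out$dosage <- g$dosage[, keep, drop = FALSE]
  out$maf <- g$maf[keep]
  out$group <- g$group[keep]
  out$mu <- g$mu[keep]
  out
}

#' Read a phenotype/covariate table
#'
#' TSV with columns `sample_id`, the response, and covariates (numeric or
#' categorical). Rows with missing covariate or response values are dropped
#' with a reported count.
#'
#' @param path file path.
#' @param response name of the response column (default `"y"`).
#' @return data.frame with attribute `"response"`.
#' @export
read_phenotypes <- function(path, response = "y") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stop("phenotype table needs a 'sample_id' column")
  if (!response %in% names(tab)) stop("response column '", response, "' not found")
  tab$sample_id <- as.character(tab$sample_id)
  cc <- stats::complete.cases(tab)
  if (any(!cc)) message("dropping ", sum(!cc), " row(s) with missing values")
  tab <- tab[cc, , drop = FALSE]
  attr(tab, "response") <- response
  tab
}

#' Read a variant-to-group map / per-variant prior means
#'
#' Group map TSV: columns `variant_id`, `group`. Prior-means TSV: columns
#' `variant_id`, `mu`.
#'
#' @param path file path.
#' @return `read_groups`: data.frame with `variant_id` and `group`;
#'   `read_prior_means`: named numeric vector.
#' @export
read_groups <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "group") %in% names(tab)))
    stop("group map needs columns 'variant_id' and 'group'")
  tab$variant_id <- as.character(tab$variant_id)
  tab$group <- as.character(tab$group)
  tab
}

#' @rdname read_groups
#' @export
read_prior_means <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "mu") %in% names(tab)))
    stop("prior-means table needs columns 'variant_id' and 'mu'")
  stats::setNames(as.numeric(tab$mu), as.character(tab$variant_id))
}

#' Assemble a model frame for the hierarchical fits
#'
#' Joins genotypes and phenotypes on sample id, imputes missing genotypes,
#' dummy-expands categorical covariates against the alphabetically first
#' level, routes grouped variants into the grouped design and handles
#' variants outside any group (`unassigned = "drop"` discards them with a
#' message, `"covariate"` adds them as singleton covariate columns; groups
#' of size 1 are always routed to the covariates).
#'
#' @param g a `geno_matrix`.
#' @param pheno a phenotype data.frame from [read_phenotypes()] (or any
#'   data.frame with `sample_id`, the response and covariates).
#' @param groups data.frame with `variant_id` and `group` (or a named list).
#' @param prior_means optional named per-variant prior means (default 1).
#' @param family a family accepted by [check_family()].
#' @param response response column name (default the table's `"response"`
#'   attribute, else `"y"`).
#' @param unassigned what to do with variants in no group.
#' @param join `"strict"` errors on any sample-id mismatch; `"intersect"`
#'   keeps the common samples with a message.
#' @return list with `y`, `covariates` (matrix), `genotypes` (imputed
#'   dosage matrix of grouped variants), `groups` (named list), `mu`,
#'   `family` and `sample_id`.
#' @export
build_model_frame <- function(g, pheno, groups, prior_means = NULL,
                              family = stats::gaussian(), response = NULL,
                              unassigned = c("drop", "covariate"),
                              join = c("strict", "intersect")) {
  unassigned <- match.arg(unassigned)
  join <- match.arg(join)
  family <- check_family(family)
  if (is.null(response)) response <- attr(pheno, "response") %||% "y"
  if (!response %in% names(pheno)) stop("response column '", response, "' not found")

  gid <- rownames(g$dosage)
  pid <- as.character(pheno$sample_id)
  common <- intersect(pid, gid)
  if (join == "strict" && (length(common) < length(pid) || length(common) < length(gid)))
    stop("sample ids differ between genotype and phenotype tables (",
         length(common), " in common); use join = 'intersect' to subset")
  if (join == "intersect" && (length(common) < length(pid) || length(common) < length(gid)))
    message("keeping ", length(common), " samples present in both tables")
  if (length(common) < 2) stop("fewer than 2 samples after id join")
  pheno <- pheno[match(common, pid), , drop = FALSE]
  g <- impute_mean(g)
  dosage <- g$dosage[common, , drop = FALSE]

  y <- pheno[[response]]
  if (family$family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial response must be coded 0/1")
  covdf <- pheno[, setdiff(names(pheno), c("sample_id", response)), drop = FALSE]
  covariates <- NULL
  if (ncol(covdf)) {
    covdf[] <- lapply(covdf, function(v)
      if (is.character(v)) factor(v, levels = sort(unique(v))) else v)
    covariates <- stats::model.matrix(~., covdf)[, -1, drop = FALSE]
  }

  if (is.data.frame(groups)) {
    gl <- split(as.character(groups$variant_id), as.character(groups$group))
  } else if (is.list(groups)) {
    gl <- groups
  } else stop("'groups' must be a data.frame or a named list")
  unknown <- setdiff(unlist(gl), colnames(dosage))
  if (length(unknown))
    stop("group map references unknown variant(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  single <- names(gl)[vapply(gl, length, 1L) < 2]
  singles <- unlist(gl[single], use.names = FALSE)
  ungrouped <- setdiff(colnames(dosage), unlist(gl))
  gl <- gl[setdiff(names(gl), single)]
  if (length(singles)) {
    message("routing singleton group(s) ", paste(single, collapse = ", "),
            " to the covariates")
    covariates <- cbind(covariates, dosage[, singles, drop = FALSE])
  }
  if (length(ungrouped)) {
    if (unassigned == "covariate") {
      covariates <- cbind(covariates, dosage[, ungrouped, drop = FALSE])
    } else {
      message("dropping ", length(ungrouped), " ungrouped variant(s)")
    }
  }
  mu <- if (is.null(prior_means)) {
    stats::setNames(rep(1, length(unlist(gl))), unlist(gl))
  } else prior_means

  list(y = y, covariates = covariates,
       genotypes = dosage[, unlist(gl), drop = FALSE],
       groups = gl, mu = mu, family = family, sample_id = common)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
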