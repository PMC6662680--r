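#' Construct a case-parent triad dataset
#'
#' The in-memory container used throughout the package: one row per nuclear
#' family, genotypes stored as variant-allele dosages (0/1/2, `NA` missing)
#' in three aligned family-by-SNP integer matrices (mother, father, child).
#' A family whose father matrix row is entirely missing is a mother-child
#' dyad. The `map` describes the SNPs (chromosome, id, genetic distance,
#' 1-based position, reference and variant allele letters) and `exposure`
#' holds family-level binary exposure columns keyed by `family_id`
#' (0/1/`NA`).
#'
#' @param mother,father,child Integer dosage matrices of equal dimension,
#'   rows named by family id and columns by SNP id.
#' @param map Data frame with columns `chr`, `snp`, `cm`, `pos`,
#'   `allele_ref`, `allele_var`, one row per SNP, in genotype column order.
#' @param exposure Data frame with column `family_id` plus one column per
#'   exposure.
#' @return An object of class `triad_dataset`.
#' @export
triad_dataset <- function(mother, father, child, map, exposure) {
  stopifnot(is.matrix(mother), is.matrix(father), is.matrix(child))
  if (!all(dim(mother) == dim(father)) || !all(dim(mother) == dim(child)))
    stop("mother, father and child matrices must have identical dimensions")
  if (nrow(map) != ncol(mother))
    stop("map must have one row per genotype column")
  need <- c("chr", "snp", "cm", "pos", "allele_ref", "allele_var")
  if (!all(need %in% names(map)))
    stop("map is missing columns: ", paste(setdiff(need, names(map)), collapse = ", "))
  if (!"family_id" %in% names(exposure))
    stop("exposure table must have a family_id column")
  if (anyDuplicated(exposure$family_id))
    stop("duplicate family ids in exposure table")
  ok <- function(g) all(is.na(g) | (g >= 0L & g <= 2L))
  if (!ok(mother) || !ok(father) || !ok(child))
    stop("genotype dosages must be 0, 1, 2 or NA")
  structure(
    list(geno = list(mother = mother, father = father, child = child),
         map = map, exposure = exposure),
    class = "triad_dataset")
}

n_families <- function(dataset) nrow(dataset$geno$mother)
n_snps <- function(dataset) ncol(dataset$geno$mother)
family_ids <- function(dataset) rownames(dataset$geno$mother)
snp_ids <- function(dataset) dataset$map$snp

# Dyad = father never genotyped (all SNP columns missing)
is_dyad <- function(dataset) rowSums(!is.na(dataset$geno$father)) == 0L

#' @export
print.triad_dataset <- function(x, ...) {
  dy <- sum(is_dyad(x))
  cat(sprintf("Case-parent triad dataset: %d families (%d complete triads, %d dyads), %d SNPs\n",
              n_families(x), n_families(x) - dy, dy, n_snps(x)))
  expo <- setdiff(names(x$exposure), "family_id")
  for (e in expo) {
    v <- x$exposure[[e]]
    cat(sprintf("  exposure '%s': %d exposed, %d unexposed, %d missing\n",
                e, sum(v == 1L, na.rm = TRUE), sum(v == 0L, na.rm = TRUE),
                sum(is.na(v))))
  }
  invisible(x)
}

# Subset a dataset to given family (rows) and/or SNP (columns) indices.
subset_dataset <- function(dataset, families = NULL, snps = NULL) {
  g <- dataset$geno
  if (!is.null(snps)) {
    g <- lapply(g, function(m) m[, snps, drop = FALSE])
    dataset$map <- dataset$map[snps, , drop = FALSE]
    rownames(dataset$map) <- NULL
  }
  if (!is.null(families)) {
    g <- lapply(g, function(m) m[families, , drop = FALSE])
    keep <- dataset$exposure$family_id %in% rownames(g$mother)
    dataset$exposure <- dataset$exposure[keep, , drop = FALSE]
    rownames(dataset$exposure) <- NULL
  }
  dataset$geno <- g
  dataset
}

# Exposure vector aligned to genotype row order for a named exposure column.
exposure_vector <- function(dataset, exposure_name) {
  if (!exposure_name %in% names(dataset$exposure))
    stop(sprintf("exposure column '%s' not found in exposure table", exposure_name))
  v <- dataset$exposure[[exposure_name]]
  v[match(family_ids(dataset), dataset$exposure$family_id)]
}
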