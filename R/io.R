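# PED/MAP + exposure-table dialect, dataset summaries, and result writers.
# PED: one row per individual -- family id, individual id, father id,
# mother id, sex, phenotype, then two allele letters per SNP ('0' missing).
# MAP: chromosome, SNP id, genetic distance, 1-based physical position.
# Exposure: TSV keyed by family_id, one 0/1/NA column per exposure.

#' Write a triad dataset as PED/MAP plus an exposure table
#'
#' @param dataset A `triad_dataset`.
#' @param prefix Path prefix; writes `<prefix>.ped`, `<prefix>.map` and
#'   `<prefix>.exposure.tsv`.
#' @return The three paths, invisibly.
#' @export
write_triad_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "triad_dataset"))
  fams <- family_ids(dataset)
  dyad <- is_dyad(dataset)
  aref <- dataset$map$allele_ref
  avar <- dataset$map$allele_var

  geno_cols <- function(g) {
    # dosage matrix -> interleaved allele-letter matrix (2 cols per SNP)
    n <- nrow(g); p <- ncol(g)
    a1 <- matrix(aref, n, p, byrow = TRUE)
    a2 <- a1
    av <- matrix(avar, n, p, byrow = TRUE)
    hi1 <- !is.na(g) & g >= 1L
    hi2 <- !is.na(g) & g == 2L
    a2[hi1] <- av[hi1]
    a1[hi2] <- av[hi2]
    a1[is.na(g)] <- "0"; a2[is.na(g)] <- "0"
    out <- matrix("", n, 2L * p)
    out[, seq(1L, 2L * p, 2L)] <- a1
    out[, seq(2L, 2L * p, 2L)] <- a2
    out
  }
  person_rows <- function(iid, fa, mo, sex, pheno, g)
    cbind(fams, iid, fa, mo, sex, pheno, geno_cols(g))

  mo_rows <- person_rows(paste0(fams, "_M"), "0", "0", 2L, 1L,
                         dataset$geno$mother)
  fa_rows <- person_rows(paste0(fams, "_F"), "0", "0", 1L, 1L,
                         dataset$geno$father)[!dyad, , drop = FALSE]
  ch_rows <- person_rows(paste0(fams, "_C"),
                         ifelse(dyad, "0", paste0(fams, "_F")),
                         paste0(fams, "_M"), 0L, 2L, dataset$geno$child)
  ped <- rbind(mo_rows, fa_rows, ch_rows)
  ped <- ped[order(ped[, 1L], ped[, 2L]), , drop = FALSE]

  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  exp_path <- paste0(prefix, ".exposure.tsv")
  utils::write.table(ped, ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  utils::write.table(dataset$map[, c("chr", "snp", "cm", "pos")], map_path,
                     quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  utils::write.table(dataset$exposure, exp_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n")
  invisible(c(ped = ped_path, map = map_path, exposure = exp_path))
}

#' Read a triad dataset from PED/MAP and an exposure table
#'
#' Families are assembled from parent/offspring id links: an individual with
#' a nonzero parent id is an offspring; its mother and (if present) father
#' rows are located by id. Genotypes are recoded to minor-allele dosage per
#' SNP, the minor allele being determined from the parents (ties broken
#' toward the lexicographically later allele letter). Non-autosomal MAP rows
#' (chromosome codes outside 1-22) are dropped with a message. A family with
#' several offspring rows keeps the first and logs the rest.
#'
#' @param ped_path,map_path,exposure_path Input file paths.
#' @return A `triad_dataset`.
#' @export
read_triad_dataset <- function(ped_path, map_path, exposure_path) {
  map <- utils::read.table(map_path, header = FALSE, sep = "",
                           col.names = c("chr", "snp", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"),
                           stringsAsFactors = FALSE)
  auto <- suppressWarnings(as.integer(map$chr)) %in% 1:22
  if (!all(auto)) {
    message(sprintf("dropping %d non-autosomal MAP row(s)", sum(!auto)))
  }
  map <- map[auto, , drop = FALSE]
  map$chr <- as.integer(map$chr)
  keep_cols <- which(auto)

  ped <- utils::read.table(ped_path, header = FALSE, sep = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  n_snp_file <- (ncol(ped) - 6L) / 2L
  if (n_snp_file != length(auto))
    stop("PED and MAP disagree on the number of SNPs")
  ids <- paste(ped[[1L]], ped[[2L]], sep = "\r")
  if (anyDuplicated(ids)) stop("duplicate individual ids in PED")

  a1 <- as.matrix(ped[, 6L + 2L * keep_cols - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * keep_cols, drop = FALSE])
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA; a2[miss] <- NA

  is_child <- ped[[3L]] != "0" | ped[[4L]] != "0"
  child_rows <- which(is_child)
  if (!length(child_rows)) stop("no offspring rows found in PED")
  fam_of_child <- ped[[1L]][child_rows]
  dup <- duplicated(fam_of_child)
  if (any(dup)) {
    warning(sprintf("%d additional offspring row(s) ignored (first child kept per family)",
                    sum(dup)))
    child_rows <- child_rows[!dup]
    fam_of_child <- fam_of_child[!dup]
  }
  locate <- function(fid, iid) {
    if (iid == "0") return(NA_integer_)
    r <- which(ped[[1L]] == fid & ped[[2L]] == iid)
    if (length(r) != 1L)
      stop(sprintf("family %s: parent id '%s' not found in PED", fid, iid))
    r
  }
  mo_rows <- mapply(locate, fam_of_child, ped[[4L]][child_rows])
  fa_rows <- mapply(locate, fam_of_child, ped[[3L]][child_rows])
  if (anyNA(mo_rows) && anyNA(fa_rows[is.na(mo_rows)]))
    stop("families with both parent ids missing are not supported")

  p <- nrow(map)
  n_fam <- length(child_rows)
  # minor allele per SNP from parents
  parent_rows <- c(mo_rows[!is.na(mo_rows)], fa_rows[!is.na(fa_rows)])
  allele_ref <- allele_var <- character(p)
  dose <- function(rows, j, var_allele) {
    d <- rep(NA_integer_, n_fam)
    has <- !is.na(rows)
    v1 <- a1[rows[has], j]; v2 <- a2[rows[has], j]
    d[has] <- (v1 == var_allele) + (v2 == var_allele)
    d
  }
  gm <- gf <- gc_ <- matrix(NA_integer_, n_fam, p,
                            dimnames = list(fam_of_child, map$snp))
  for (j in seq_len(p)) {
    al <- c(a1[parent_rows, j], a2[parent_rows, j])
    al <- al[!is.na(al)]
    lev <- sort(unique(al))
    if (length(lev) > 2L)
      stop(sprintf("SNP %s has more than two alleles", map$snp[j]))
    if (length(lev) == 0L) lev <- c("?", "?")
    if (length(lev) == 1L) lev <- c(lev, "?")     # monomorphic in parents
    counts <- c(sum(al == lev[1L]), sum(al == lev[2L]))
    # minor allele is the variant; tie -> lexicographically later letter
    var_idx <- if (counts[2L] <= counts[1L]) 2L else 1L
    allele_var[j] <- lev[var_idx]
    allele_ref[j] <- lev[3L - var_idx]
    gm[, j] <- dose(mo_rows, j, allele_var[j])
    gf[, j] <- dose(fa_rows, j, allele_var[j])
    gc_[, j] <- dose(child_rows, j, allele_var[j])
  }
  map$allele_ref <- allele_ref
  map$allele_var <- allele_var

  expo <- utils::read.table(exposure_path, header = TRUE, sep = "\t",
                            na.strings = c("NA", ""),
                            colClasses = c(family_id = "character"),
                            stringsAsFactors = FALSE)
  triad_dataset(gm, gf, gc_, map, expo)
}

#' Summarize a triad dataset in the style of a study-description table
#'
#' Counts families, complete triads, dyads and genotyped individuals
#' (3 per triad, 2 per dyad), and for each exposure the numbers of exposed
#' and missing mothers -- per level of an optional subset column (e.g.
#' ethnicity) plus a pooled row.
#'
#' @param dataset A `triad_dataset`.
#' @param exposures Exposure column names (default: all).
#' @param subset_col Optional grouping column in the exposure table.
#' @return A data frame, one row per subset level plus `"pooled"`.
#' @export
dataset_summary <- function(dataset, exposures = NULL, subset_col = NULL) {
  stopifnot(inherits(dataset, "triad_dataset"))
  expo_tab <- dataset$exposure
  if (is.null(exposures))
    exposures <- setdiff(names(expo_tab), c("family_id", subset_col))
  dyad <- is_dyad(dataset)
  ord <- match(family_ids(dataset), expo_tab$family_id)
  groups <- if (is.null(subset_col)) rep("pooled", n_families(dataset))
            else as.character(expo_tab[[subset_col]][ord])
  level_names <- if (is.null(subset_col)) "pooled"
                 else c(sort(unique(groups)), "pooled")
  one <- function(sel) {
    nt <- sum(!dyad[sel]); nd <- sum(dyad[sel])
    row <- data.frame(families = nt + nd, complete_triads = nt, dyads = nd,
                      individuals = 3L * nt + 2L * nd)
    for (e in exposures) {
      v <- expo_tab[[e]][ord][sel]
      row[[paste0(e, "_exposed")]] <- sum(v == 1L, na.rm = TRUE)
      row[[paste0(e, "_missing")]] <- sum(is.na(v))
    }
    row
  }
  rows <- lapply(level_names, function(lv) {
    sel <- if (lv == "pooled") rep(TRUE, length(groups)) else groups == lv
    cbind(data.frame(subset = lv, stringsAsFactors = FALSE), one(sel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write scan results, QC reports and power tables as TSV
#'
#' Writers emit a fixed column order, tab separators, `"\n"` line endings
#' and `NA` for missing values, so identical inputs give byte-identical
#' files.
#'
#' @param x The object to write (a scan data frame, `qc_report`, or power
#'   curve table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(x, path) {
  if (inherits(x, "qc_report")) x <- x$metrics
  utils::write.table(as.data.frame(x), path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n")
  invisible(path)
}

#' Write a QC exclusion report in the two-column table layout
#'
#' @param report A `qc_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  th <- report$thresholds
  tab <- data.frame(
    item = c("Total number of SNPs",
             sprintf("Failed HWE test (p<%g)", th$hwe_p_min),
             sprintf("More than %g%% missing calls", 100 * th$missing_max),
             sprintf("MAF less than %g%%", 100 * th$maf_min),
             "r2=1 with flanking SNPs",
             sprintf("Mendelian errors detected (>%g%%)", 100 * th$mendel_max),
             "Number of SNPs remaining after quality control"),
    count = c(report$total_snps, report$counts[["hwe"]],
              report$counts[["missing"]], report$counts[["maf"]],
              report$counts[["ld"]], report$counts[["mendel"]],
              report$remaining_snps),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write a machine-readable provenance record for a pipeline run
#'
#' @param path Output JSON path.
#' @param ... Named fields (inputs, thresholds, seed, stage counts).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, ...) {
  obj <- list(package = "pooxe",
              version = as.character(utils::packageVersion("pooxe")),
              ...)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
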