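# SNP-level quality control: exact Hardy-Weinberg test, Mendelian-error
# screening, call-rate and MAF filters, and perfect-LD pruning.
# Allele-frequency-based metrics (MAF, HWE, LD) use parents only: the
# children are ascertained cases and not independent of their parents.

#' Exact test for Hardy-Weinberg equilibrium
#'
#' The exact conditional test on the heterozygote count: fixing the total
#' number of individuals and of minor alleles, the two-sided p-value is the
#' sum of the probabilities of all heterozygote counts (of the same parity)
#' that are no more probable than the observed one under the HWE null.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (any labeling; the rarer allele is
#'   identified internally). Total must be positive.
#' @return The exact p-value in (0, 1\]; a monomorphic sample returns 1 (the
#'   only possible configuration).
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (n_AA < 0 || n_Aa < 0 || n_aa < 0) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("at least one genotyped individual is required")
  na <- 2 * n_aa + n_Aa                 # minor-allele count (after folding)
  if (na > n) na <- 2 * n - na
  if (na == 0) return(1)
  # heterozygote counts sharing the parity of the minor-allele total
  h_obs <- n_Aa
  h_all <- seq(na %% 2, na, by = 2)
  n_hom_rare <- (na - h_all) / 2
  n_hom_comm <- n - h_all - n_hom_rare
  valid <- n_hom_comm >= 0
  h_all <- h_all[valid]
  # log P(h) up to a constant: multinomial coefficient times 2^h
  lp <- h_all * log(2) - lgamma(n_hom_rare[valid] + 1) -
    lgamma(h_all + 1) - lgamma(n_hom_comm[valid] + 1)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  p_obs <- pr[match(h_obs, h_all)]
  if (is.na(p_obs)) stop("observed heterozygote count is inconsistent with the allele total")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

#' Mendelian-error rate of one SNP across families
#'
#' A family's genotype triple (mother, father, child dosages) is a
#' Mendelian error when the child dosage falls outside the interval implied
#' by obligate transmissions: at least one variant copy per homozygous
#'-variant parent, at most one per parent carrying the variant. Families
#' with any missing member at the SNP are skipped.
#'
#' @param mother,father,child Dosage vectors (0/1/2/`NA`) over families.
#' @return Proportion of complete families with an impossible triple.
#' @export
mendel_error_rate <- function(mother, father, child) {
  complete <- !is.na(mother) & !is.na(father) & !is.na(child)
  if (!any(complete)) stop("no family has complete genotypes at this SNP")
  m <- mother[complete]; f <- father[complete]; k <- child[complete]
  cmin <- (m == 2L) + (f == 2L)
  cmax <- (m >= 1L) + (f >= 1L)
  mean(k < cmin | k > cmax)
}

# TRUE per complete family if its triple is Mendelian-inconsistent.
mendel_error_flags <- function(mother, father, child) {
  cmin <- (mother == 2L) + (father == 2L)
  cmax <- (mother >= 1L) + (father >= 1L)
  bad <- child < cmin | child > cmax
  bad & !is.na(bad)
}

#' Prune SNPs in perfect linkage disequilibrium with a flanking SNP
#'
#' For each SNP pair within `window` positions in map order, the squared
#' Pearson correlation of parental dosages is computed on pairwise-complete
#' observations; when it equals 1 (within 1e-12) the later SNP is dropped
#' and the earlier retained. Pairs involving a zero-variance SNP are skipped
#' (correlation undefined) and counted in the `"n_skipped_pairs"` attribute.
#'
#' @param parent_geno Numeric matrix of parental dosages, individuals by
#'   SNPs, in map order.
#' @param window Number of flanking SNPs compared on each side (default 5).
#' @return Integer vector of retained column indices, with attribute
#'   `n_skipped_pairs`.
#' @export
ld_prune_perfect <- function(parent_geno, window = 5L) {
  p <- ncol(parent_geno)
  if (p < 1L) stop("at least one SNP is required")
  dropped <- logical(p)
  skipped <- 0L
  for (i in seq_len(p)) {
    if (dropped[i]) next
    jmax <- min(i + window, p)
    if (jmax <= i) next
    for (j in (i + 1L):jmax) {
      if (dropped[j]) next
      ok <- !is.na(parent_geno[, i]) & !is.na(parent_geno[, j])
      if (sum(ok) < 2L) { skipped <- skipped + 1L; next }
      xi <- parent_geno[ok, i]; xj <- parent_geno[ok, j]
      if (stats::var(xi) == 0 || stats::var(xj) == 0) {
        skipped <- skipped + 1L
        next
      }
      if (stats::cor(xi, xj)^2 >= 1 - 1e-12) dropped[j] <- TRUE
    }
  }
  out <- which(!dropped)
  attr(out, "n_skipped_pairs") <- skipped
  out
}

#' Default quality-control thresholds
#'
#' @param missing_max Maximum fraction of missing calls (default 0.05).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param hwe_p_min SNPs with exact HWE p below this fail (default 0.001).
#' @param mendel_max Maximum Mendelian-error rate (default 0.01).
#' @param ld_window Flanking window for perfect-LD pruning (default 5).
#' @return A list of thresholds for [run_qc()].
#' @export
qc_thresholds <- function(missing_max = 0.05, maf_min = 0.05,
                          hwe_p_min = 0.001, mendel_max = 0.01,
                          ld_window = 5L) {
  list(missing_max = missing_max, maf_min = maf_min, hwe_p_min = hwe_p_min,
       mendel_max = mendel_max, ld_window = as.integer(ld_window))
}

#' Run SNP-level quality control on a triad dataset
#'
#' Applies, in order: call-rate, MAF, HWE, Mendelian-error filters, then
#' perfect-LD pruning on the survivors. Each criterion is counted
#' independently (a SNP can fail several) but a SNP is removed once.
#' Families with a Mendelian-inconsistent triple at a retained SNP have
#' that SNP's genotypes set to missing in the filtered dataset.
#'
#' @param dataset A `triad_dataset`.
#' @param thresholds A [qc_thresholds()] list.
#' @return An object of class `qc_report`: `total_snps`, per-criterion
#'   `counts`, `remaining_snps`, per-SNP `metrics` data frame, the
#'   `thresholds`, and the filtered `dataset`.
#' @export
run_qc <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "triad_dataset"))
  p <- n_snps(dataset)
  if (p < 1L) stop("dataset contains no SNPs")
  gm <- dataset$geno$mother
  gf <- dataset$geno$father
  gc_ <- dataset$geno$child
  dyad <- is_dyad(dataset)
  # genotyped individuals: mothers, children, and fathers of complete triads
  gf_typed <- gf[!dyad, , drop = FALSE]
  n_ind <- nrow(gm) + nrow(gc_) + nrow(gf_typed)
  miss_frac <- (colSums(is.na(gm)) + colSums(is.na(gc_)) +
                  colSums(is.na(gf_typed))) / n_ind

  parents <- rbind(gm, gf_typed)
  p_var <- colMeans(parents, na.rm = TRUE) / 2
  maf <- pmin(p_var, 1 - p_var)
  hwe_p <- vapply(seq_len(p), function(j) {
    g <- parents[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
  mendel <- vapply(seq_len(p), function(j) {
    if (all(dyad)) return(0)
    mendel_error_rate(gm[!dyad, j], gf[!dyad, j], gc_[!dyad, j])
  }, numeric(1))

  fail_missing <- miss_frac > thresholds$missing_max
  fail_maf <- is.na(maf) | maf < thresholds$maf_min
  fail_hwe <- !is.na(hwe_p) & hwe_p < thresholds$hwe_p_min
  fail_mendel <- mendel > thresholds$mendel_max
  survivors <- which(!(fail_missing | fail_maf | fail_hwe | fail_mendel))

  fail_ld <- logical(p)
  if (length(survivors) >= 2L) {
    kept <- ld_prune_perfect(parents[, survivors, drop = FALSE],
                             thresholds$ld_window)
    fail_ld[survivors[-kept]] <- TRUE
  }
  excluded <- fail_missing | fail_maf | fail_hwe | fail_mendel | fail_ld
  retained <- which(!excluded)

  excluded_by <- vapply(seq_len(p), function(j) {
    paste(c("missing", "maf", "hwe", "mendel", "ld")[
      c(fail_missing[j], fail_maf[j], fail_hwe[j], fail_mendel[j], fail_ld[j])],
      collapse = ","
    )
  }, character(1))
  metrics <- data.frame(
    snp_id = snp_ids(dataset),
    call_rate_missing_fraction = miss_frac,
    maf = maf,
    hwe_p = hwe_p,
    mendel_error_rate = mendel,
    excluded_by = excluded_by,
    stringsAsFactors = FALSE
  )
  rownames(metrics) <- NULL

  filtered <- subset_dataset(dataset, snps = retained)
  # blank out Mendelian-inconsistent family genotypes at retained SNPs
  if (length(retained) && any(!dyad)) {
    for (jj in seq_along(retained)) {
      j <- retained[jj]
      bad <- mendel_error_flags(gm[, j], gf[, j], gc_[, j])
      if (any(bad)) {
        filtered$geno$mother[bad, jj] <- NA_integer_
        filtered$geno$father[bad, jj] <- NA_integer_
        filtered$geno$child[bad, jj] <- NA_integer_
      }
    }
  }

  out <- list(
    total_snps = p,
    counts = c(hwe = sum(fail_hwe), missing = sum(fail_missing),
               maf = sum(fail_maf), ld = sum(fail_ld),
               mendel = sum(fail_mendel)),
    remaining_snps = length(retained),
    metrics = metrics,
    thresholds = thresholds,
    dataset = filtered
  )
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf("Total number of SNPs\t%d\n", x$total_snps))
  cat("Criteria:\n")
  cat(sprintf("  Failed HWE test (p<%g)\t%d\n", th$hwe_p_min, x$counts[["hwe"]]))
  cat(sprintf("  More than %g%% missing calls\t%d\n", 100 * th$missing_max,
              x$counts[["missing"]]))
  cat(sprintf("  MAF less than %g%%\t%d\n", 100 * th$maf_min, x$counts[["maf"]]))
  cat(sprintf("  r2=1 with flanking SNPs\t%d\n", x$counts[["ld"]]))
  cat(sprintf("  Mendelian errors detected (>%g%%)\t%d\n",
              100 * th$mendel_max, x$counts[["mendel"]]))
  cat(sprintf("Number of SNPs remaining after quality control\t%d\n",
              x$remaining_snps))
  cat("(a SNP can fail several criteria but is removed once)\n")
  invisible(x)
}
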