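# Effect estimates and Wald tests built from stratum fits:
#   PoO    : RRR_PoO   = RR_mat / RR_pat            (one stratum, or overall)
#   PoOxE  : RRR_PoOxE = RRR_PoO(E) / RRR_PoO(U)
#   Child  : RR under the RR_mat = RR_pat constraint, pooled strata
#   GxE    : ratio of constrained RRs, exposed / unexposed
# All tests are two-sided Wald tests on the log scale.

default_target <- function(fit) {
  nr <- names(fit$log_rr_mat)
  nr[which.max(fit$freq[nr])]
}

# var(log RR_mat[t] - log RR_pat[t]) from the estimation-scale covariance
poo_var <- function(fit, target) {
  if (fit$constrained)
    stop("parent-of-origin contrast undefined for a constrained (RR_mat=RR_pat) fit")
  m <- paste0("rrm:", target); p <- paste0("rrp:", target)
  fit$vcov[m, m] + fit$vcov[p, p] - 2 * fit$vcov[m, p]
}

wald_row <- function(log_est, se, conf_level) {
  z <- log_est / se
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = exp(log_est),
       ci_low = exp(log_est - zq * se),
       ci_high = exp(log_est + zq * se),
       se_log = se, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Parent-of-origin effect from one stratum fit
#'
#' Estimates `RRR_PoO = RR_mat / RR_pat` for a target haplotype from an
#' unconstrained [fit_stratum()] result, with a two-sided Wald test of
#' `RRR_PoO = 1`. The standard error comes from the fit's covariance:
#' `var(log RR_mat) + var(log RR_pat) - 2 cov`.
#'
#' @param fit A converged, unconstrained `stratum_fit`.
#' @param target Haplotype label (default: most frequent non-reference).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A one-row data frame: `target`, `reference`, `rrr_poo`, `ci_low`,
#'   `ci_high`, `se_log`, `z`, `p_value`, `converged`.
#' @export
poo_effect <- function(fit, target = NULL, conf_level = 0.95) {
  stopifnot(inherits(fit, "stratum_fit"))
  if (is.null(target)) target <- default_target(fit)
  if (!target %in% names(fit$log_rr_mat))
    stop(sprintf("'%s' is not a non-reference haplotype of this fit", target))
  if (!fit$converged) {
    return(data.frame(target = target, reference = fit$reference,
                      rrr_poo = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      se_log = NA_real_, z = NA_real_, p_value = NA_real_,
                      converged = FALSE, stringsAsFactors = FALSE))
  }
  ld <- fit$log_rr_mat[[target]] - fit$log_rr_pat[[target]]
  w <- wald_row(ld, sqrt(poo_var(fit, target)), conf_level)
  data.frame(target = target, reference = fit$reference,
             rrr_poo = w$estimate, ci_low = w$ci_low, ci_high = w$ci_high,
             se_log = w$se_log, z = w$z, p_value = w$p,
             converged = TRUE, stringsAsFactors = FALSE)
}

#' Wald test of a parent-of-origin by exposure interaction
#'
#' Combines unconstrained fits of the exposed and unexposed strata into the
#' interaction estimate `RRR_PoOxE = RRR_PoO(exposed) / RRR_PoO(unexposed)`.
#' The strata contain disjoint families, so the squared standard errors add:
#' `se^2 = se_E^2 + se_U^2`, `z = log RRR_PoOxE / se`, two-sided normal p.
#'
#' @param fit_exposed,fit_unexposed Unconstrained `stratum_fit` objects over
#'   the same haplotype space.
#' @param target Haplotype label (default: most frequent non-reference of
#'   the exposed fit).
#' @param conf_level Confidence level (default 0.95).
#' @param marker Optional marker id carried into the output.
#' @return A one-row data frame of class `pooxe_result` with the per-stratum
#'   `RRR_PoO` estimates and intervals, `rrr_pooxe` with `ci_low`/`ci_high`,
#'   `wald_z`, `p_value`, `q_value` (`NA` until [add_q_values()]), and
#'   `effect_type = "PoOxE"`.
#' @export
pooxe_test <- function(fit_exposed, fit_unexposed, target = NULL,
                       conf_level = 0.95, marker = NA_character_) {
  stopifnot(inherits(fit_exposed, "stratum_fit"),
            inherits(fit_unexposed, "stratum_fit"))
  if (!identical(fit_exposed$hap_labels, fit_unexposed$hap_labels) ||
      !identical(fit_exposed$reference, fit_unexposed$reference))
    stop("exposed and unexposed fits use different haplotype spaces")
  if (is.null(target)) target <- default_target(fit_exposed)
  pe <- poo_effect(fit_exposed, target, conf_level)
  pu <- poo_effect(fit_unexposed, target, conf_level)
  ok <- pe$converged && pu$converged
  if (ok) {
    ld <- log(pe$rrr_poo) - log(pu$rrr_poo)
    se <- sqrt(pe$se_log^2 + pu$se_log^2)
    w <- wald_row(ld, se, conf_level)
  } else {
    w <- list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              se_log = NA_real_, z = NA_real_, p = NA_real_)
  }
  out <- data.frame(
    marker = marker,
    target = target, reference = fit_exposed$reference,
    rrr_poo_exposed = pe$rrr_poo,
    poo_exposed_lo = pe$ci_low, poo_exposed_hi = pe$ci_high,
    rrr_poo_unexposed = pu$rrr_poo,
    poo_unexposed_lo = pu$ci_low, poo_unexposed_hi = pu$ci_high,
    rrr_pooxe = w$estimate, ci_low = w$ci_low, ci_high = w$ci_high,
    se_log = w$se_log, wald_z = w$z, p_value = w$p, q_value = NA_real_,
    effect_type = "PoOxE",
    n_exposed = fit_exposed$n_families, n_unexposed = fit_unexposed$n_families,
    converged = ok, stringsAsFactors = FALSE)
  class(out) <- c("pooxe_result", "data.frame")
  out
}

#' Child-effect and gene-environment interaction tests
#'
#' Both use the constrained model in which a haplotype carries one relative
#' risk regardless of parental origin (`constrain_poo = TRUE` in
#' [fit_stratum()]). The child effect is that RR from the pooled fit of both
#' strata; GxE is the ratio of the constrained RRs, exposed over unexposed,
#' tested exactly as the interaction ratio in [pooxe_test()].
#'
#' @param fit_exposed,fit_unexposed Constrained per-stratum `stratum_fit`s.
#' @param fit_pooled Constrained fit of both strata combined.
#' @param target Haplotype label (default from `fit_pooled`).
#' @param conf_level Confidence level (default 0.95).
#' @param marker Optional marker id.
#' @return A two-row data frame (`effect_type` `"Child"`, `"GxE"`) with
#'   `estimate`, `ci_low`, `ci_high`, `wald_z`, `p_value`.
#' @export
child_and_gxe_tests <- function(fit_exposed, fit_unexposed, fit_pooled,
                                target = NULL, conf_level = 0.95,
                                marker = NA_character_) {
  for (f in list(fit_exposed, fit_unexposed, fit_pooled))
    if (!f$constrained)
      stop("child/GxE tests require constrained (RR_mat = RR_pat) fits")
  if (is.null(target)) target <- default_target(fit_pooled)
  rr_name <- paste0("rr:", target)
  one <- function(fit) {
    list(lrr = fit$log_rr_mat[[target]], v = fit$vcov[rr_name, rr_name])
  }
  ch <- one(fit_pooled)
  wc <- wald_row(ch$lrr, sqrt(ch$v), conf_level)
  e <- one(fit_exposed); u <- one(fit_unexposed)
  wg <- wald_row(e$lrr - u$lrr, sqrt(e$v + u$v), conf_level)
  data.frame(
    marker = marker, target = target, reference = fit_pooled$reference,
    effect_type = c("Child", "GxE"),
    estimate = c(wc$estimate, wg$estimate),
    ci_low = c(wc$ci_low, wg$ci_low),
    ci_high = c(wc$ci_high, wg$ci_high),
    wald_z = c(wc$z, wg$z),
    p_value = c(wc$p, wg$p),
    stringsAsFactors = FALSE)
}

# Genotype submatrices for one marker (columns snp_idx) in given family rows.
marker_geno <- function(dataset, snp_idx, rows) {
  list(m = dataset$geno$mother[rows, snp_idx, drop = FALSE],
       f = dataset$geno$father[rows, snp_idx, drop = FALSE],
       c = dataset$geno$child[rows, snp_idx, drop = FALSE])
}

#' Stratified effect table for one SNP or haplotype
#'
#' Produces the four stratified estimates for a marker -- Child, GxE, PoO and
#' PoOxE -- in one table: the child effect and GxE from constrained fits, the
#' overall PoO effect from an unconstrained fit of all exposure-known
#' families, and PoOxE from the per-stratum unconstrained fits. Families with
#' missing exposure are excluded.
#'
#' @param dataset A `triad_dataset`.
#' @param snps SNP ids (1-3) forming the marker.
#' @param exposure_name Name of the exposure column.
#' @param conf_level Confidence level (default 0.95).
#' @param ... Passed to [fit_stratum()].
#' @return A four-row data frame with columns `marker`, `target`,
#'   `reference`, `frequency`, `effect_type`, `estimate`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
effect_table <- function(dataset, snps, exposure_name, conf_level = 0.95, ...) {
  stopifnot(inherits(dataset, "triad_dataset"))
  idx <- match(snps, snp_ids(dataset))
  if (anyNA(idx)) stop("unknown SNP id(s): ",
                       paste(snps[is.na(idx)], collapse = ", "))
  expo <- exposure_vector(dataset, exposure_name)
  if (all(is.na(expo))) stop("exposure column contains no observed values")
  keep <- which(!is.na(expo))
  expo <- expo[keep]
  g <- marker_geno(dataset, idx, keep)
  aref <- dataset$map$allele_ref[idx]
  avar <- dataset$map$allele_var[idx]
  fitfun <- function(rows, constrain, label)
    fit_stratum(g$m[rows, , drop = FALSE], g$f[rows, , drop = FALSE],
                g$c[rows, , drop = FALSE], allele_ref = aref,
                allele_var = avar, constrain_poo = constrain,
                stratum = label, ...)
  e_rows <- expo == 1L; u_rows <- expo == 0L
  marker <- paste(snps, collapse = "-")
  fit_all <- fitfun(rep(TRUE, length(expo)), FALSE, "pooled")
  fit_e <- fitfun(e_rows, FALSE, "exposed")
  fit_u <- fitfun(u_rows, FALSE, "unexposed")
  fit_all_c <- fitfun(rep(TRUE, length(expo)), TRUE, "pooled")
  fit_e_c <- fitfun(e_rows, TRUE, "exposed")
  fit_u_c <- fitfun(u_rows, TRUE, "unexposed")
  target <- default_target(fit_all)

  cg <- child_and_gxe_tests(fit_e_c, fit_u_c, fit_all_c, target, conf_level,
                            marker)
  po <- poo_effect(fit_all, target, conf_level)
  px <- pooxe_test(fit_e, fit_u, target, conf_level, marker)
  data.frame(
    marker = marker,
    target = target, reference = fit_all$reference,
    frequency = unname(fit_all$freq[target]),
    effect_type = c("Child", "GxE", "PoO", "PoOxE"),
    estimate = c(cg$estimate, po$rrr_poo, px$rrr_pooxe),
    ci_low = c(cg$ci_low, po$ci_low, px$ci_low),
    ci_high = c(cg$ci_high, po$ci_high, px$ci_high),
    p_value = c(cg$p_value, po$p_value, px$p_value),
    stringsAsFactors = FALSE)
}

#' Genome-wide scan for parent-of-origin by exposure interactions
#'
#' Fits the unconstrained triad model separately in the exposed and
#' unexposed strata at every marker (each SNP, or each sliding window of
#' `window_size` adjacent SNPs in haplotype mode) and performs the Wald
#' PoOxE test. Families whose exposure is missing are excluded from the scan
#' for that exposure. Markers whose fit fails are kept in the output with a
#' `note` and an `NA` p-value.
#'
#' @param dataset A (typically QC-filtered) `triad_dataset`.
#' @param exposure_name Exposure column to stratify on.
#' @param mode `"snp"` (default) or `"haplotype"`.
#' @param window_size Number of adjacent SNPs per haplotype window (2 or 3).
#' @param conf_level Confidence level (default 0.95).
#' @param ... Passed to [fit_stratum()].
#' @return A data frame of class `pooxe_scan`, one row per marker, with
#'   chromosome/position, target and reference labels (minor alleles
#'   lowercase), per-stratum `RRR_PoO`, `rrr_pooxe` with confidence
#'   interval, `wald_z`, `p_value` and a `q_value` column filled by
#'   [add_q_values()].
#' @examples
#' ds <- simulate_dataset(sim_params(150, 80, n_null_snps = 3, seed = 11))
#' head(scan_pooxe(ds, "exposure"))
#' @export
scan_pooxe <- function(dataset, exposure_name, mode = c("snp", "haplotype"),
                       window_size = 2L, conf_level = 0.95, ...) {
  stopifnot(inherits(dataset, "triad_dataset"))
  mode <- match.arg(mode)
  expo <- exposure_vector(dataset, exposure_name)
  if (all(is.na(expo))) stop("exposure column contains no observed values")
  keep <- which(!is.na(expo))
  expo <- expo[keep]
  e_rows <- expo == 1L; u_rows <- expo == 0L
  if (!any(e_rows) || !any(u_rows))
    stop("both an exposed and an unexposed stratum are required")

  nsnp <- n_snps(dataset)
  if (mode == "snp") {
    windows <- as.list(seq_len(nsnp))
  } else {
    if (!window_size %in% 2:3) stop("window_size must be 2 or 3")
    if (nsnp < window_size) stop("fewer SNPs than the window size")
    windows <- lapply(seq_len(nsnp - window_size + 1L),
                      function(i) i:(i + window_size - 1L))
  }

  rows <- vector("list", length(windows))
  for (wi in seq_along(windows)) {
    idx <- windows[[wi]]
    ids <- snp_ids(dataset)[idx]
    marker <- paste(ids, collapse = "-")
    g <- marker_geno(dataset, idx, keep)
    aref <- dataset$map$allele_ref[idx]
    avar <- dataset$map$allele_var[idx]
    res <- tryCatch({
      fe <- fit_stratum(g$m[e_rows, , drop = FALSE], g$f[e_rows, , drop = FALSE],
                        g$c[e_rows, , drop = FALSE], allele_ref = aref,
                        allele_var = avar, stratum = "exposed", ...)
      fu <- fit_stratum(g$m[u_rows, , drop = FALSE], g$f[u_rows, , drop = FALSE],
                        g$c[u_rows, , drop = FALSE], allele_ref = aref,
                        allele_var = avar, stratum = "unexposed", ...)
      r <- pooxe_test(fe, fu, conf_level = conf_level, marker = marker)
      # minor haplotypes printed lowercase, as in standard triad reports
      r$target <- casefold_label(r$target, fe$freq, fu$freq,
                                 fe$n_families, fu$n_families)
      r$note <- ""
      r
    }, error = function(e) {
      out <- empty_scan_row(marker)
      out$note <- conditionMessage(e)
      out
    })
    res$chr <- dataset$map$chr[idx[1L]]
    res$pos <- dataset$map$pos[idx[1L]]
    rows[[wi]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  front <- c("marker", "chr", "pos")
  out <- out[, c(front, setdiff(names(out), front))]
  class(out) <- c("pooxe_scan", "data.frame")
  out
}

empty_scan_row <- function(marker) {
  data.frame(marker = marker, target = NA_character_, reference = NA_character_,
             rrr_poo_exposed = NA_real_, poo_exposed_lo = NA_real_,
             poo_exposed_hi = NA_real_, rrr_poo_unexposed = NA_real_,
             poo_unexposed_lo = NA_real_, poo_unexposed_hi = NA_real_,
             rrr_pooxe = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             se_log = NA_real_, wald_z = NA_real_, p_value = NA_real_,
             q_value = NA_real_, effect_type = "PoOxE",
             n_exposed = NA_integer_, n_unexposed = NA_integer_,
             converged = FALSE, stringsAsFactors = FALSE)
}

# Lowercase per-locus alleles of a haplotype label when the haplotype is
# minor (pooled frequency < 0.5) -- the Table-style display convention.
casefold_label <- function(label, freq_e, freq_u, n_e, n_u) {
  f <- (freq_e[label] * n_e + freq_u[label] * n_u) / (n_e + n_u)
  if (!is.na(f) && f < 0.5) tolower(label) else toupper(label)
}

#' Top markers of a scan
#'
#' @param scan A `pooxe_scan` result.
#' @param n Number of rows (default 20, the usual report size).
#' @return The `n` markers with the smallest p-values.
#' @export
top_hits <- function(scan, n = 20L) {
  scan <- scan[order(scan$p_value), , drop = FALSE]
  utils::head(scan, n)
}
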