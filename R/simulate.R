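#' Simulation parameters for synthetic case-parent triad data
#'
#' Bundles the design of a synthetic triad/dyad dataset: stratum sizes
#' (maternal exposure is a family-level design variable, so each stratum has
#' an exact number of families), the variant allele frequency, and the
#' per-stratum relative risks for a maternally (`rr_mat`) and paternally
#' (`rr_pat`) inherited copy of the variant allele. The implied
#' parent-of-origin effect in a stratum is `RRR_PoO = rr_mat / rr_pat`, and
#' the interaction effect across strata is
#' `RRR_PoOxE = RRR_PoO(exposed) / RRR_PoO(unexposed)`.
#'
#' Defaults follow the reference single-SNP design used throughout the
#' package's power and calibration work: 1100 unexposed and 500 exposed
#' complete triads at minor allele frequency 0.2.
#'
#' @param n_unexposed_families Number of families with unexposed mothers.
#' @param n_exposed_families Number of families with exposed mothers.
#' @param variant_allele_freq Variant allele frequency, either a scalar
#'   (both strata) or length-2 vector `c(unexposed, exposed)`; in (0,1).
#' @param rr_mat Relative risk per maternally inherited variant allele;
#'   scalar or length-2 `c(unexposed, exposed)`.
#' @param rr_pat Relative risk per paternally inherited variant allele;
#'   scalar or length-2 `c(unexposed, exposed)`.
#' @param dyad_fraction Probability that a family's father is ungenotyped
#'   (mother-child dyad); missing completely at random.
#' @param exposure_missing_fraction Probability that a family's recorded
#'   exposure is missing (the latent stratum still drives generation).
#' @param n_null_snps Number of SNPs simulated with all relative risks 1.
#' @param n_effect_snps Number of SNPs simulated with the `rr_mat`/`rr_pat`
#'   parameters above.
#' @param genotype_error_rate Probability that a genotype call is perturbed
#'   by a random allele flip (see [inject_errors()]).
#' @param seed Integer seed making the simulated dataset reproducible.
#' @return An object of class `sim_params` (a validated list).
#' @seealso [simulate_dataset()], [triad_state_distribution()]
#' @export
sim_params <- function(n_unexposed_families = 1100,
                       n_exposed_families = 500,
                       variant_allele_freq = 0.2,
                       rr_mat = 1,
                       rr_pat = 1,
                       dyad_fraction = 0,
                       exposure_missing_fraction = 0,
                       n_null_snps = 1,
                       n_effect_snps = 0,
                       genotype_error_rate = 0,
                       seed = 1L) {
  two <- function(x) if (length(x) == 1L) rep(x, 2L) else x
  p <- two(variant_allele_freq)
  rm_ <- two(rr_mat)
  rp_ <- two(rr_pat)
  stopifnot(
    length(p) == 2L, length(rm_) == 2L, length(rp_) == 2L,
    n_unexposed_families >= 0, n_exposed_families >= 0,
    n_null_snps >= 0, n_effect_snps >= 0,
    n_null_snps + n_effect_snps >= 1
  )
  if (any(p <= 0 | p >= 1))
    stop("variant_allele_freq must lie strictly in (0, 1)")
  if (any(rm_ <= 0) || any(rp_ <= 0))
    stop("relative risks must be strictly positive")
  for (pr in c(dyad_fraction, exposure_missing_fraction, genotype_error_rate))
    if (pr < 0 || pr > 1) stop("fractions must lie in [0, 1]")
  out <- list(
    n_unexposed_families = as.integer(n_unexposed_families),
    n_exposed_families = as.integer(n_exposed_families),
    variant_allele_freq = p,
    rr_mat = rm_,
    rr_pat = rp_,
    dyad_fraction = dyad_fraction,
    exposure_missing_fraction = exposure_missing_fraction,
    n_null_snps = as.integer(n_null_snps),
    n_effect_snps = as.integer(n_effect_snps),
    genotype_error_rate = genotype_error_rate,
    seed = as.integer(seed)
  )
  class(out) <- "sim_params"
  out
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic triad design\n")
  cat(sprintf("  families: %d unexposed + %d exposed (dyad fraction %.3g)\n",
              x$n_unexposed_families, x$n_exposed_families, x$dyad_fraction))
  cat(sprintf("  variant allele freq (U, E): %.3g, %.3g\n",
              x$variant_allele_freq[1], x$variant_allele_freq[2]))
  cat(sprintf("  RR_mat (U, E): %.3g, %.3g;  RR_pat (U, E): %.3g, %.3g\n",
              x$rr_mat[1], x$rr_mat[2], x$rr_pat[1], x$rr_pat[2]))
  rrr_poo <- x$rr_mat / x$rr_pat
  cat(sprintf("  implied RRR_PoO (U, E): %.3g, %.3g;  RRR_PoOxE: %.3g\n",
              rrr_poo[1], rrr_poo[2], rrr_poo[2] / rrr_poo[1]))
  cat(sprintf("  SNPs: %d null + %d effect; genotype error rate %.3g; seed %d\n",
              x$n_null_snps, x$n_effect_snps, x$genotype_error_rate, x$seed))
  invisible(x)
}

#' Distribution of latent parental transmissions in a case triad
#'
#' Under Hardy-Weinberg equilibrium, random mating and a multiplicative
#' risk per inherited variant allele, the four latent alleles of a case
#' triad -- maternal transmitted `t_m`, maternal untransmitted `u_m`,
#' paternal transmitted `t_f`, paternal untransmitted `u_f`, each 0/1
#' copies of the variant -- have joint probability proportional to
#' `p^s (1-p)^(4-s) * rr_mat^t_m * rr_pat^t_f` with `s = t_m+u_m+t_f+u_f`.
#' The normalizing constant is `(1-p+p*rr_mat) * (1-p+p*rr_pat)` in closed
#' form.
#'
#' @param p Variant allele frequency, strictly in (0,1).
#' @param rr_mat,rr_pat Relative risk per maternally / paternally inherited
#'   variant allele; strictly positive.
#' @return A data frame with 16 rows and columns `t_m`, `u_m`, `t_f`, `u_f`,
#'   `prob`; probabilities sum to 1. The closed-form normalizer is attached
#'   as attribute `"normalizer"`.
#' @examples
#' d <- triad_state_distribution(0.2, rr_mat = 2, rr_pat = 1)
#' sum(d$prob)  # 1
#' @export
triad_state_distribution <- function(p, rr_mat, rr_pat) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("p must be a single number strictly in (0, 1)")
  if (rr_mat <= 0 || rr_pat <= 0)
    stop("relative risks must be strictly positive")
  states <- expand.grid(t_m = 0:1, u_m = 0:1, t_f = 0:1, u_f = 0:1,
                        KEEP.OUT.ATTRS = FALSE)
  s <- states$t_m + states$u_m + states$t_f + states$u_f
  w <- p^s * (1 - p)^(4 - s) * rr_mat^states$t_m * rr_pat^states$t_f
  norm <- (1 - p + p * rr_mat) * (1 - p + p * rr_pat)
  states$prob <- w / norm
  attr(states, "normalizer") <- norm
  states
}

#' Simulate a case-parent triad/dyad dataset with known truth
#'
#' Draws families i.i.d. within each exposure stratum from
#' [triad_state_distribution()], collapses latent transmissions to observed
#' genotype dosages (mother `M = t_m + u_m`, father `F = t_f + u_f`, child
#' `C = t_m + t_f`), masks fathers in a `dyad_fraction` of families, and
#' optionally perturbs genotype calls. SNPs are mutually independent
#' (no linkage disequilibrium is simulated): null SNPs use relative risks 1,
#' effect SNPs the design's `rr_mat`/`rr_pat`.
#'
#' @param params A [sim_params()] object.
#' @return A `triad_dataset` (see [triad_dataset()]) with an additional
#'   `truth` element recording the generating parameters and which SNP ids
#'   carry the effect.
#' @examples
#' ds <- simulate_dataset(sim_params(n_unexposed_families = 50,
#'                                   n_exposed_families = 20, seed = 7))
#' ds
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n_u <- params$n_unexposed_families
  n_e <- params$n_exposed_families
  n_fam <- n_u + n_e
  if (n_fam < 1L) stop("at least one family is required")
  stratum <- rep(c(0L, 1L), c(n_u, n_e))
  n_snp <- params$n_null_snps + params$n_effect_snps
  is_effect <- rep(c(FALSE, TRUE), c(params$n_null_snps, params$n_effect_snps))
  snp_ids <- sprintf("snp%04d", seq_len(n_snp))
  fam_ids <- sprintf("fam%05d", seq_len(n_fam))

  states <- expand.grid(t_m = 0:1, u_m = 0:1, t_f = 0:1, u_f = 0:1,
                        KEEP.OUT.ATTRS = FALSE)
  gm <- gf <- gc_ <- matrix(NA_integer_, n_fam, n_snp,
                            dimnames = list(fam_ids, snp_ids))
  for (s in 1:2) {   # 1 = unexposed, 2 = exposed
    idx <- which(stratum == s - 1L)
    if (!length(idx)) next
    for (j in seq_len(n_snp)) {
      rm_ <- if (is_effect[j]) params$rr_mat[s] else 1
      rp_ <- if (is_effect[j]) params$rr_pat[s] else 1
      pr <- triad_state_distribution(params$variant_allele_freq[s], rm_, rp_)$prob
      k <- sample.int(16L, length(idx), replace = TRUE, prob = pr)
      gm[idx, j] <- states$t_m[k] + states$u_m[k]
      gf[idx, j] <- states$t_f[k] + states$u_f[k]
      gc_[idx, j] <- states$t_m[k] + states$t_f[k]
    }
  }

  father_missing <- stats::runif(n_fam) < params$dyad_fraction
  gf[father_missing, ] <- NA_integer_

  exposure_obs <- stratum
  exposure_obs[stats::runif(n_fam) < params$exposure_missing_fraction] <- NA_integer_

  map <- data.frame(
    chr = 1L,
    snp = snp_ids,
    cm = 0,
    pos = 10000L * seq_len(n_snp),
    allele_ref = "A",
    allele_var = "C",
    stringsAsFactors = FALSE
  )
  ds <- triad_dataset(
    mother = gm, father = gf, child = gc_,
    map = map,
    exposure = data.frame(family_id = fam_ids, exposure = exposure_obs,
                          stringsAsFactors = FALSE)
  )
  ds$truth <- list(params = params, effect_snps = snp_ids[is_effect],
                   stratum = stratum)
  if (params$genotype_error_rate > 0) {
    err_seed <- (params$seed + 104729L) %% .Machine$integer.max
    ds <- inject_errors(ds, params$genotype_error_rate, seed = err_seed)
  }
  ds
}

#' Randomly perturb genotype calls to exercise quality control
#'
#' Each non-missing genotype call (one person at one SNP) is independently
#' perturbed with probability `rate` by flipping one randomly chosen allele:
#' dosage 0 becomes 1, dosage 2 becomes 1, and dosage 1 becomes 0 or 2 with
#' equal probability. This creates Mendelian inconsistencies and departures
#' from Hardy-Weinberg proportions without touching the input object.
#'
#' @param dataset A `triad_dataset`.
#' @param rate Per-call perturbation probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A new `triad_dataset`; the input is not modified.
#' @export
inject_errors <- function(dataset, rate, seed = 1L) {
  stopifnot(inherits(dataset, "triad_dataset"))
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (rate == 0) return(dataset)
  set.seed(as.integer(seed))
  flip_one <- function(g) {
    obs <- which(!is.na(g))
    hit <- obs[stats::runif(length(obs)) < rate]
    if (length(hit)) {
      cur <- g[hit]
      new <- ifelse(cur == 0L, 1L,
             ifelse(cur == 2L, 1L,
                    ifelse(stats::runif(length(cur)) < 0.5, 0L, 2L)))
      g[hit] <- new
    }
    g
  }
  out <- dataset
  out$geno$mother <- flip_one(dataset$geno$mother)
  out$geno$father <- flip_one(dataset$geno$father)
  out$geno$child <- flip_one(dataset$geno$child)
  out
}
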