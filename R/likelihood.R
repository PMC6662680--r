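# Maximum-likelihood machinery for the case-parent triad model with
# parent-of-origin relative risks.
#
# Latent state of one case family: the four transmitted/untransmitted
# haplotypes (t_m, u_m, t_f, u_f), each an index into the haplotype set.
# Conditional on the child being a case,
#   pi(state) = f(t_m) f(u_m) f(t_f) f(u_f) RR_mat(t_m) RR_pat(t_f) / Z,
#   Z = (sum_h f(h) RR_mat(h)) * (sum_h f(h) RR_pat(h)).
# Equivalently the four slots are independent draws: t_m ~ g_m, u_m ~ f,
# t_f ~ g_f, u_f ~ f with g(h) = f(h) RR(h) / sum f RR. This tilted-slot
# factorization gives the EM algorithm a fully closed-form M-step.

# --- state indexing -------------------------------------------------------

# Index tables for the H^4 latent states; t_m varies fastest.
state_index <- function(H) {
  g <- expand.grid(tm = seq_len(H), um = seq_len(H),
                   tf = seq_len(H), uf = seq_len(H),
                   KEEP.OUT.ATTRS = FALSE)
  list(tm = g$tm, um = g$um, tf = g$tf, uf = g$uf, H = H, S = H^4)
}

state_probs <- function(freq, rr_mat, rr_pat, st) {
  pi <- freq[st$tm] * freq[st$um] * freq[st$tf] * freq[st$uf] *
    rr_mat[st$tm] * rr_pat[st$tf]
  pi / (sum(freq * rr_mat) * sum(freq * rr_pat))
}

# H x H logical: is the unordered pair (h1, h2) compatible with the observed
# multilocus dosage genotype g (NA = untyped locus, marginalized)?
pair_compat <- function(alleles, g) {
  H <- nrow(alleles)
  pc <- matrix(TRUE, H, H)
  for (l in seq_along(g)) {
    if (is.na(g[l])) next
    pc <- pc & (outer(alleles[, l], alleles[, l], "+") == g[l])
  }
  pc
}

# Compatibility of each latent state with one family's observed genotypes.
family_compat <- function(alleles, gm, gf, gc, st) {
  pcM <- pair_compat(alleles, gm)
  pcF <- pair_compat(alleles, gf)
  pcC <- pair_compat(alleles, gc)
  pcM[cbind(st$tm, st$um)] & pcF[cbind(st$tf, st$uf)] & pcC[cbind(st$tm, st$tf)]
}

# Aggregate families into distinct observed-genotype patterns.
# Returns the pattern-by-state 0/1 matrix, per-pattern counts, and the
# number of families incompatible with every state (skipped with warning
# by callers: Mendelian errors that survived upstream checks).
aggregate_patterns <- function(gm, gf, gc, alleles, st) {
  key <- apply(cbind(gm, gf, gc), 1L, paste, collapse = ",")
  tab <- table(key)
  pats <- names(tab)
  first <- match(pats, key)
  PM <- matrix(0, length(pats), st$S)
  for (i in seq_along(pats)) {
    r <- first[i]
    PM[i, ] <- as.numeric(family_compat(alleles, gm[r, ], gf[r, ], gc[r, ], st))
  }
  ok <- rowSums(PM) > 0
  n_bad <- sum(as.integer(tab)[!ok])
  list(PM = PM[ok, , drop = FALSE], counts = as.numeric(tab)[ok],
       n_incompatible = n_bad)
}

# --- parameter packing (estimation scale) ---------------------------------
# theta = (additive log-ratio of freq vs reference,
#          log RR_mat non-reference, log RR_pat non-reference)  [free model]
# theta = (alr freq, log RR non-reference)                      [rr_mat=rr_pat]

pack_theta <- function(freq, rr_mat, rr_pat, ref, constrained) {
  alr <- log(freq[-ref] / freq[ref])
  if (constrained) c(alr, log(rr_mat[-ref]))
  else c(alr, log(rr_mat[-ref]), log(rr_pat[-ref]))
}

unpack_theta <- function(theta, H, ref, constrained) {
  k <- H - 1L
  e <- exp(theta[seq_len(k)])
  freq <- numeric(H)
  freq[-ref] <- e / (1 + sum(e))
  freq[ref] <- 1 / (1 + sum(e))
  rr_mat <- rr_pat <- rep(1, H)
  if (constrained) {
    rr_mat[-ref] <- rr_pat[-ref] <- exp(theta[k + seq_len(k)])
  } else {
    rr_mat[-ref] <- exp(theta[k + seq_len(k)])
    rr_pat[-ref] <- exp(theta[2L * k + seq_len(k)])
  }
  list(freq = freq, rr_mat = rr_mat, rr_pat = rr_pat)
}

theta_names <- function(labels, ref, constrained) {
  lab <- labels[-ref]
  if (constrained) c(paste0("f:", lab), paste0("rr:", lab))
  else c(paste0("f:", lab), paste0("rrm:", lab), paste0("rrp:", lab))
}

# --- log-likelihoods ------------------------------------------------------

#' Complete-data log-likelihood of latent triad states
#'
#' Log-likelihood of fully observed latent states (transmitted and
#' untransmitted haplotypes of both parents) under the triad model. States
#' are indexed in `expand.grid(t_m, u_m, t_f, u_f)` order with `t_m` varying
#' fastest; each index runs over the haplotypes in the order of `freq`.
#'
#' @param state_counts Nonnegative counts per latent state, length `H^4`.
#' @param freq Haplotype frequency vector (sums to 1).
#' @param rr_mat,rr_pat Relative-risk vectors aligned to `freq` (reference
#'   entry 1).
#' @return The log-likelihood; `-Inf` if a zero-probability state has
#'   positive count.
#' @export
complete_data_loglik <- function(state_counts, freq, rr_mat, rr_pat) {
  H <- length(freq)
  stopifnot(length(state_counts) == H^4, all(state_counts >= 0),
            length(rr_mat) == H, length(rr_pat) == H)
  st <- state_index(H)
  pi <- state_probs(freq, rr_mat, rr_pat, st)
  pos <- state_counts > 0
  if (any(pi[pos] <= 0)) return(-Inf)
  sum(state_counts[pos] * log(pi[pos]))
}

#' Observed-data log-likelihood for triad/dyad families
#'
#' Sums, for each family, the latent-state probabilities compatible with its
#' observed (possibly incomplete and unphased) genotypes: a missing father is
#' marginalized over all genotypes, and heterozygote phase ambiguity is
#' summed over. Families compatible with no state (Mendelian inconsistencies
#' that survived quality control) are skipped and counted in the
#' `"n_skipped"` attribute.
#'
#' @param mother,father,child Dosage vectors (single SNP) or matrices with
#'   one column per locus; `NA` marks a missing genotype.
#' @param freq Haplotype frequency vector over the `2^L` haplotypes in
#'   `expand.grid` order over loci (first locus varying fastest; allele 0 =
#'   reference, 1 = variant).
#' @param rr_mat,rr_pat Relative-risk vectors aligned to `freq`.
#' @return Total log-likelihood with attribute `n_skipped`.
#' @export
observed_data_loglik <- function(mother, father, child, freq, rr_mat, rr_pat) {
  gm <- as_geno_matrix(mother)
  gf <- as_geno_matrix(father)
  gc_ <- as_geno_matrix(child)
  L <- ncol(gm)
  H <- length(freq)
  stopifnot(H == 2^L, length(rr_mat) == H, length(rr_pat) == H)
  alleles <- hap_alleles(L)
  st <- state_index(H)
  ag <- aggregate_patterns(gm, gf, gc_, alleles, st)
  if (ag$n_incompatible > 0)
    warning(sprintf("%d famil%s compatible with no latent state; skipped",
                    ag$n_incompatible, if (ag$n_incompatible == 1) "y" else "ies"))
  pi <- state_probs(freq, rr_mat, rr_pat, st)
  lik <- as.vector(ag$PM %*% pi)
  ll <- sum(ag$counts * log(lik))
  attr(ll, "n_skipped") <- ag$n_incompatible
  ll
}

as_geno_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "integer"
    x
  } else matrix(as.integer(x), ncol = 1L)
}

# 2^L x L matrix of variant-allele counts per haplotype (first locus fastest).
hap_alleles <- function(L) {
  as.matrix(expand.grid(rep(list(0:1), L), KEEP.OUT.ATTRS = FALSE))
}

hap_labels <- function(alleles, allele_ref, allele_var) {
  apply(alleles, 1L, function(a)
    paste(ifelse(a == 1L, allele_var, allele_ref), collapse = "-"))
}

# --- fitting --------------------------------------------------------------

#' Fit the parent-of-origin triad model in one exposure stratum
#'
#' Maximum-likelihood estimation of haplotype frequencies and per-origin
#' relative risks (`RR_mat`, `RR_pat` per non-reference haplotype) from
#' case-parent triads and dyads, by EM over latent transmitted/untransmitted
#' haplotypes (default) or direct quasi-Newton maximization of the observed
#' log-likelihood; the two routes maximize the same function and agree. The
#' covariance of the estimates on the estimation scale (additive-log-ratio
#' frequencies, log relative risks) is the inverse of the numerically
#' differentiated observed information at the optimum.
#'
#' Families with both parents missing are excluded; families compatible with
#' no latent state are skipped and counted. For multi-SNP haplotypes an
#' initial frequency-only EM pass estimates haplotype frequencies; haplotypes
#' below `frequency_floor` are then removed from the space (they are
#' effectively unobserved) and the most frequent haplotype becomes the
#' reference.
#'
#' @param mother,father,child Dosage vectors (one SNP) or one-column-per-locus
#'   matrices (1-3 SNPs); rows are families.
#' @param allele_ref,allele_var Allele letters per locus used to label
#'   haplotypes (defaults `"A"`/`"a"`).
#' @param constrain_poo If `TRUE`, fit a single relative risk per haplotype
#'   regardless of parental origin (`RR_mat = RR_pat`), the model used for
#'   child-effect and GxE estimates.
#' @param method `"em"` (default) or `"bfgs"`.
#' @param tol Convergence tolerance on the observed log-likelihood
#'   improvement (EM) / `optim` `reltol` seed (BFGS).
#' @param max_iter Maximum EM iterations.
#' @param frequency_floor Haplotype frequency below which a multi-SNP
#'   haplotype is removed from the space (default 0.01).
#' @param stratum Optional label (e.g. `"exposed"`) carried into the result.
#' @return An object of class `stratum_fit` with elements `freq` (named),
#'   `log_rr_mat`, `log_rr_pat` (named by non-reference haplotype),
#'   `vcov` (estimation-scale), `loglik`, `n_families`, `n_skipped`,
#'   `converged`, `iterations`, `reference`, `hap_labels`, `constrained`,
#'   `stratum`.
#' @examples
#' ds <- simulate_dataset(sim_params(300, 0, rr_mat = 2, n_null_snps = 0,
#'                                   n_effect_snps = 1, seed = 3))
#' f <- fit_stratum(ds$geno$mother[, 1], ds$geno$father[, 1], ds$geno$child[, 1])
#' exp(f$log_rr_mat)  # near the simulated RR_mat of 2
#' @export
fit_stratum <- function(mother, father, child,
                        allele_ref = NULL, allele_var = NULL,
                        constrain_poo = FALSE,
                        method = c("em", "bfgs"),
                        tol = 1e-8, max_iter = 5000L,
                        frequency_floor = 0.01,
                        stratum = NA_character_) {
  method <- match.arg(method)
  gm <- as_geno_matrix(mother)
  gf <- as_geno_matrix(father)
  gc_ <- as_geno_matrix(child)
  L <- ncol(gm)
  if (L > 3L) stop("haplotypes of more than 3 SNPs are not supported")
  if (is.null(allele_ref)) allele_ref <- rep("A", L)
  if (is.null(allele_var)) allele_var <- rep("a", L)

  # exclude families with both parents entirely missing (uninterpretable
  # for the triad design: only triads and single-parent dyads enter)
  both_missing <- rowSums(!is.na(gm)) == 0L & rowSums(!is.na(gf)) == 0L
  n_parents_missing <- sum(both_missing)
  if (n_parents_missing > 0L) {
    gm <- gm[!both_missing, , drop = FALSE]
    gf <- gf[!both_missing, , drop = FALSE]
    gc_ <- gc_[!both_missing, , drop = FALSE]
  }
  if (nrow(gm) < 1L) stop("no informative families")

  # monomorphic loci have no estimable risk
  counts_var <- colSums(gm, na.rm = TRUE) + colSums(gf, na.rm = TRUE) +
    colSums(gc_, na.rm = TRUE)
  n_obs <- colSums(!is.na(gm)) + colSums(!is.na(gf)) + colSums(!is.na(gc_))
  if (any(counts_var == 0L) || any(counts_var == 2L * n_obs))
    stop("monomorphic locus: relative risks are not estimable")

  alleles <- hap_alleles(L)
  labels <- hap_labels(alleles, allele_ref, allele_var)

  # initial haplotype frequencies: allele-frequency product, refined by a
  # frequency-only EM for unphased multi-SNP data
  p_loc <- counts_var / (2 * n_obs)
  f0 <- apply(alleles, 1L, function(a) prod(ifelse(a == 1L, p_loc, 1 - p_loc)))
  st <- state_index(nrow(alleles))
  ag <- aggregate_patterns(gm, gf, gc_, alleles, st)
  if (L > 1L) {
    f0 <- em_frequency_only(ag, st, f0, iters = 50L)
    keep <- f0 >= frequency_floor
    if (sum(keep) < 2L)
      stop("fewer than two haplotypes above the frequency floor")
    if (!all(keep)) {
      alleles <- alleles[keep, , drop = FALSE]
      labels <- labels[keep]
      st <- state_index(nrow(alleles))
      ag <- aggregate_patterns(gm, gf, gc_, alleles, st)
      f0 <- f0[keep] / sum(f0[keep])
    }
  }
  if (ag$n_incompatible > 0)
    warning(sprintf("%d famil%s compatible with no latent state; skipped",
                    ag$n_incompatible, if (ag$n_incompatible == 1) "y" else "ies"))
  if (nrow(ag$PM) == 0L) stop("no families compatible with the haplotype space")

  H <- nrow(alleles)
  ref <- which.max(f0)

  negll <- function(theta) {
    par <- unpack_theta(theta, H, ref, constrain_poo)
    pi <- state_probs(par$freq, par$rr_mat, par$rr_pat, st)
    lik <- as.vector(ag$PM %*% pi)
    if (any(lik <= 0)) return(1e12)
    -sum(ag$counts * log(lik))
  }

  theta0 <- pack_theta(f0, rep(1, H), rep(1, H), ref, constrain_poo)
  if (method == "em") {
    emres <- em_fit(ag, st, f0, ref, constrain_poo, tol, max_iter)
    theta_hat <- pack_theta(emres$freq, emres$rr_mat, emres$rr_pat, ref,
                            constrain_poo)
    loglik <- emres$loglik
    converged <- emres$converged
    iterations <- emres$iterations
  } else {
    opt <- stats::optim(theta0, negll, method = "BFGS",
                        control = list(maxit = 1000L, reltol = 1e-12))
    theta_hat <- opt$par
    loglik <- -opt$value
    converged <- opt$convergence == 0L
    iterations <- as.integer(opt$counts[["function"]])
  }

  par <- unpack_theta(theta_hat, H, ref, constrain_poo)
  vcov <- tryCatch({
    hess <- stats::optimHess(theta_hat, negll)
    solve(hess)
  }, error = function(e) {
    warning("observed information not invertible; covariance unavailable")
    matrix(NA_real_, length(theta_hat), length(theta_hat))
  })
  nm <- theta_names(labels, ref, constrain_poo)
  dimnames(vcov) <- list(nm, nm)

  freq <- stats::setNames(par$freq, labels)
  lab_nr <- labels[-ref]
  out <- list(
    freq = freq,
    log_rr_mat = stats::setNames(log(par$rr_mat[-ref]), lab_nr),
    log_rr_pat = stats::setNames(log(par$rr_pat[-ref]), lab_nr),
    vcov = vcov,
    loglik = loglik,
    n_families = sum(ag$counts),
    n_skipped = ag$n_incompatible,
    n_parents_missing = n_parents_missing,
    converged = converged,
    iterations = iterations,
    reference = labels[ref],
    hap_labels = labels,
    constrained = constrain_poo,
    stratum = stratum,
    method = method
  )
  class(out) <- "stratum_fit"
  out
}

# Frequency-only EM (all RR = 1): used to seed/prune the haplotype space.
em_frequency_only <- function(ag, st, f0, iters = 50L) {
  f <- f0 / sum(f0)
  N <- sum(ag$counts)
  for (i in seq_len(iters)) {
    pi <- state_probs(f, rep(1, st$H), rep(1, st$H), st)
    lik <- as.vector(ag$PM %*% pi)
    if (any(lik <= 0)) break
    w <- ag$counts / lik
    s <- pi * as.vector(crossprod(ag$PM, w))
    n_slot <- slot_counts(s, st)
    f_new <- n_slot$tm + n_slot$um + n_slot$tf + n_slot$uf
    f_new <- pmax(f_new, 1e-12)
    f_new <- f_new / sum(f_new)
    if (max(abs(f_new - f)) < 1e-9) { f <- f_new; break }
    f <- f_new
  }
  f
}

slot_counts <- function(s, st) {
  H <- st$H
  cnt <- function(idx) {
    out <- numeric(H)
    agg <- rowsum(s, idx)
    out[as.integer(rownames(agg))] <- agg[, 1L]
    out
  }
  list(tm = cnt(st$tm), um = cnt(st$um), tf = cnt(st$tf), uf = cnt(st$uf))
}

# EM with closed-form M-step via the tilted-slot factorization:
#   f from the two untransmitted slots, g_m/g_f from the transmitted slots,
#   RR = (g / f) normalized to the reference haplotype.
em_fit <- function(ag, st, f0, ref, constrained, tol, max_iter) {
  H <- st$H
  f <- f0 / sum(f0)
  rr_mat <- rr_pat <- rep(1, H)
  N <- sum(ag$counts)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    pi <- state_probs(f, rr_mat, rr_pat, st)
    lik <- as.vector(ag$PM %*% pi)
    ll <- sum(ag$counts * log(lik))
    if (ll < ll_old - 1e-7)
      warning(sprintf("EM log-likelihood decreased at iteration %d", it))
    if (is.finite(ll_old) && ll - ll_old < tol) {
      ll_old <- ll
      converged <- TRUE
      break
    }
    ll_old <- ll
    # E-step: expected latent-state counts
    w <- ag$counts / lik
    s <- pi * as.vector(crossprod(ag$PM, w))
    n_slot <- slot_counts(s, st)
    # M-step: closed form in the (f, g_m, g_f) parameterization
    f_new <- pmax(n_slot$um + n_slot$uf, 1e-12)
    f_new <- f_new / sum(f_new)
    if (constrained) {
      g <- pmax(n_slot$tm + n_slot$tf, 1e-12)
      g <- g / sum(g)
      rr <- (g / f_new) / (g[ref] / f_new[ref])
      rr_mat <- rr_pat <- rr
    } else {
      g_m <- pmax(n_slot$tm, 1e-12) / N
      g_f <- pmax(n_slot$tf, 1e-12) / N
      rr_mat <- (g_m / f_new) / (g_m[ref] / f_new[ref])
      rr_pat <- (g_f / f_new) / (g_f[ref] / f_new[ref])
    }
    f <- f_new
  }
  list(freq = f, rr_mat = rr_mat, rr_pat = rr_pat, loglik = ll_old,
       converged = converged, iterations = it)
}

#' @export
print.stratum_fit <- function(x, ...) {
  cat(sprintf("Triad model fit%s: %d families, loglik %.4f (%s, %d iter%s)\n",
              if (!is.na(x$stratum)) paste0(" [", x$stratum, "]") else "",
              x$n_families, x$loglik, x$method, x$iterations,
              if (x$converged) "" else ", NOT CONVERGED"))
  cat(sprintf("  reference haplotype: %s\n", x$reference))
  tab <- data.frame(
    haplotype = names(x$freq),
    freq = round(unname(x$freq), 4)
  )
  nr <- names(x$log_rr_mat)
  tab$RR_mat <- round(exp(x$log_rr_mat)[match(tab$haplotype, nr)], 3)
  tab$RR_pat <- round(exp(x$log_rr_pat)[match(tab$haplotype, nr)], 3)
  if (x$constrained) names(tab)[3:4] <- c("RR", "RR.1")
  print(tab, row.names = FALSE)
  invisible(x)
}

# Serialize a stratum_fit to JSON for audit trails.
#' @export
#' @rdname fit_stratum
#' @param fit A `stratum_fit`.
#' @param path Output JSON path.
write_stratum_fit <- function(fit, path) {
  stopifnot(inherits(fit, "stratum_fit"))
  obj <- fit
  obj$vcov <- list(names = rownames(fit$vcov), matrix = unclass(fit$vcov))
  class(obj) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
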