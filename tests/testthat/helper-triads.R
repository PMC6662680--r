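# Shared fixtures and small oracles, built in code.

# Simulate one dataset and fit both exposure strata at one SNP.
fit_both_strata <- function(params, snp = 1L, ...) {
  ds <- simulate_dataset(params)
  g <- ds$geno
  ex <- ds$truth$stratum   # design stratum, immune to exposure missingness
  list(
    exposed = fit_stratum(g$mother[ex == 1L, snp], g$father[ex == 1L, snp],
                          g$child[ex == 1L, snp], stratum = "exposed", ...),
    unexposed = fit_stratum(g$mother[ex == 0L, snp], g$father[ex == 0L, snp],
                            g$child[ex == 0L, snp], stratum = "unexposed", ...),
    dataset = ds
  )
}

# Deterministic per-replicate seed schedule below 2^31.
rep_seeds <- function(base_seed, n) (base_seed + 7919L * seq_len(n)) %% 2147483647L

# Independent enumeration oracle for the exact HWE test: full conditional
# distribution of the heterozygote count given n diploids and na minor
# alleles, via binomial coefficients (a different route than the package's
# multinomial-kernel normalization).
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  if (na > n) na <- 2 * n - na
  if (na == 0) return(1)
  h <- seq(na %% 2, na, by = 2)
  naa_r <- (na - h) / 2
  keep <- naa_r + h <= n
  h <- h[keep]; naa_r <- naa_r[keep]
  # ways to form naa_r rare homozygotes, h heterozygotes, rest common
  # homozygotes, times 2^h orderings within heterozygotes
  lp <- lchoose(n, naa_r) + lchoose(n - naa_r, h) + h * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

# Brute-force observed likelihood of one family by direct enumeration over
# the 16 latent single-SNP states (independent of the package's pattern
# machinery).
brute_family_loglik <- function(M, F_, C, p, rr_mat, rr_pat) {
  d <- triad_state_distribution(p, rr_mat, rr_pat)
  ok <- rep(TRUE, nrow(d))
  if (!is.na(M)) ok <- ok & (d$t_m + d$u_m == M)
  if (!is.na(F_)) ok <- ok & (d$t_f + d$u_f == F_)
  if (!is.na(C)) ok <- ok & (d$t_m + d$t_f == C)
  log(sum(d$prob[ok]))
}
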