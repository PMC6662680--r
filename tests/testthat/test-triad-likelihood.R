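# Likelihood machinery: closed forms, latent-state marginalization, EM.

test_that("complete-data log-likelihood has its closed forms", {
  # uniform everything: every state has probability 1/H^4
  H <- 2
  cnt <- rep(3, H^4)
  ll <- complete_data_loglik(cnt, rep(1 / H, H), rep(1, H), rep(1, H))
  expect_equal(ll, sum(cnt) * log(1 / H^4), tolerance = 1e-12)

  # single-SNP p = 0.2, rr_mat = 2: normalizer 1.2 shows up in each state
  d <- triad_state_distribution(0.2, 2, 1)
  cnt1 <- numeric(16); cnt1[5] <- 1   # any single state
  ll1 <- complete_data_loglik(cnt1, c(0.8, 0.2), c(1, 2), c(1, 1))
  expect_equal(ll1, log(d$prob[5]), tolerance = 1e-12)

  # relabelling invariance: permuting haplotypes with their parameters
  freq <- c(0.55, 0.25, 0.15, 0.05)
  rrm <- c(1, 2, 0.5, 1.4); rrp <- c(1, 0.7, 1.1, 3)
  set.seed(9); cnt4 <- rpois(4^4, 2)
  perm <- c(3, 1, 4, 2)
  st <- expand.grid(tm = 1:4, um = 1:4, tf = 1:4, uf = 1:4)
  inv <- order(perm)
  idx_perm <- inv[st$tm] + 4 * (inv[st$um] - 1) + 16 * (inv[st$tf] - 1) +
    64 * (inv[st$uf] - 1)
  cnt_perm <- numeric(4^4)
  cnt_perm[idx_perm] <- cnt4
  expect_equal(
    complete_data_loglik(cnt4, freq, rrm, rrp),
    complete_data_loglik(cnt_perm, freq[perm], rrm[perm], rrp[perm]),
    tolerance = 1e-10)

  expect_identical(complete_data_loglik(cnt1, c(1, 0), c(1, 2), c(1, 1)), -Inf)
})

test_that("observed-data likelihood marginalizes latent states correctly", {
  p <- 0.3; rrm <- 1.7; rrp <- 0.8
  freq <- c(1 - p, p); rm2 <- c(1, rrm); rp2 <- c(1, rrp)

  # complete unambiguous triad = its unique latent state
  ll <- observed_data_loglik(2, 0, 1, freq, rm2, rp2)
  expect_equal(as.numeric(ll), brute_family_loglik(2, 0, 1, p, rrm, rrp),
               tolerance = 1e-12)

  # mother-child dyad = brute-force father marginalization
  for (mc in list(c(1, 0), c(1, 1), c(2, 1), c(0, 0))) {
    ll_d <- observed_data_loglik(mc[1], NA_integer_, mc[2], freq, rm2, rp2)
    expect_equal(as.numeric(ll_d),
                 brute_family_loglik(mc[1], NA, mc[2], p, rrm, rrp),
                 tolerance = 1e-12)
  }

  # dyad likelihood equals the sum of the triad likelihood over all fathers
  lik_sum <- sum(vapply(0:2, function(f_)
    exp(brute_family_loglik(1, f_, 1, p, rrm, rrp)), numeric(1)))
  expect_equal(as.numeric(observed_data_loglik(1, NA_integer_, 1, freq, rm2, rp2)),
               log(lik_sum), tolerance = 1e-12)

  # triple heterozygote with rr_mat = rr_pat: both origins contribute equally
  d <- triad_state_distribution(p, 1.5, 1.5)
  mat_origin <- d$prob[d$t_m == 1 & d$u_m == 0 & d$t_f == 0 & d$u_f == 1]
  pat_origin <- d$prob[d$t_m == 0 & d$u_m == 1 & d$t_f == 1 & d$u_f == 0]
  expect_equal(mat_origin, pat_origin, tolerance = 1e-14)
  ll_het <- observed_data_loglik(1, 1, 1, freq, c(1, 1.5), c(1, 1.5))
  expect_equal(as.numeric(ll_het), log(2 * mat_origin), tolerance = 1e-12)

  # Mendelian-inconsistent family skipped with a warning
  expect_warning(observed_data_loglik(c(0, 1), c(0, 0), c(2, 1),
                                      freq, rm2, rp2),
                 "compatible with no latent state")
})

test_that("EM and quasi-Newton maximize the same likelihood", {
  fits <- fit_both_strata(sim_params(600, 300, rr_mat = c(1, 2),
                                     n_null_snps = 0, n_effect_snps = 1,
                                     seed = 404))
  g <- fits$dataset$geno
  ex <- fits$dataset$truth$stratum
  fb <- fit_stratum(g$mother[ex == 1, 1], g$father[ex == 1, 1],
                    g$child[ex == 1, 1], method = "bfgs")
  fe <- fits$exposed
  expect_true(fe$converged && fb$converged)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-6)
  expect_equal(fe$log_rr_mat, fb$log_rr_mat, tolerance = 1e-3)
  expect_equal(fe$log_rr_pat, fb$log_rr_pat, tolerance = 1e-3)
  expect_equal(fe$freq, fb$freq, tolerance = 1e-4)
})

test_that("null data recover log relative risks near zero", {
  fits <- fit_both_strata(sim_params(2500, 2500, seed = 11))
  for (f in list(fits$exposed, fits$unexposed)) {
    se_m <- sqrt(f$vcov["rrm:a", "rrm:a"])
    se_p <- sqrt(f$vcov["rrp:a", "rrp:a"])
    expect_lt(abs(f$log_rr_mat[["a"]]), 4 * se_m)
    expect_lt(abs(f$log_rr_pat[["a"]]), 4 * se_p)
    expect_true(all(eigen(f$vcov, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
    expect_equal(sum(f$freq), 1, tolerance = 1e-10)
  }
})

test_that("EM matches a dense grid search on a tiny dataset", {
  # six families chosen to keep the optimum interior
  M <- c(1, 1, 2, 0, 1, 1)
  F_ <- c(0, 1, 1, 1, 2, 0)
  C <- c(1, 1, 2, 1, 1, 0)
  fit <- fit_stratum(M, F_, C)
  ll_fun <- function(p, rm_, rp_)
    as.numeric(observed_data_loglik(M, F_, C, c(1 - p, p), c(1, rm_), c(1, rp_)))
  # coarse pass, then refinement around the argmax
  best <- c(0.5, 1, 1); span <- list(p = c(0.05, 0.95), l = c(-2.5, 2.5))
  for (stage in 1:3) {
    pg <- seq(max(0.02, best[1] - diff(span$p) / 8),
              min(0.98, best[1] + diff(span$p) / 8), length.out = 21)
    lg <- seq(log(best[2]) - diff(span$l) / 8,
              log(best[2]) + diff(span$l) / 8, length.out = 21)
    lg2 <- seq(log(best[3]) - diff(span$l) / 8,
               log(best[3]) + diff(span$l) / 8, length.out = 21)
    if (stage == 1) {
      pg <- seq(0.05, 0.95, length.out = 31)
      lg <- lg2 <- seq(-2.5, 2.5, length.out = 31)
    }
    grid <- expand.grid(p = pg, lm = lg, lp = lg2)
    vals <- mapply(function(p, lm, lp) ll_fun(p, exp(lm), exp(lp)),
                   grid$p, grid$lm, grid$lp)
    k <- which.max(vals)
    best <- c(grid$p[k], exp(grid$lm[k]), exp(grid$lp[k]))
  }
  ll_grid <- max(vals)
  expect_gte(fit$loglik, ll_grid - 1e-9)   # grid points are feasible points
  expect_lt(abs(fit$loglik - ll_grid), 1e-3)
})

test_that("swapping parental roles swaps the fitted origin effects", {
  ds <- simulate_dataset(sim_params(700, 0, variant_allele_freq = 0.25,
                                    rr_mat = 2.2, rr_pat = 0.8,
                                    n_null_snps = 0, n_effect_snps = 1,
                                    seed = 88))
  g <- ds$geno
  f1 <- fit_stratum(g$mother[, 1], g$father[, 1], g$child[, 1])
  f2 <- fit_stratum(g$father[, 1], g$mother[, 1], g$child[, 1])
  expect_equal(f1$log_rr_mat, f2$log_rr_pat, tolerance = 1e-7)
  expect_equal(f1$log_rr_pat, f2$log_rr_mat, tolerance = 1e-7)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
})

test_that("dyads and constrained fits integrate into estimation", {
  # with 30% fathers missing the fit still recovers the null
  fits <- fit_both_strata(sim_params(2000, 1000, dyad_fraction = 0.3,
                                     seed = 21))
  f <- fits$unexposed
  expect_gt(f$n_families, 0)
  expect_lt(abs(f$log_rr_mat[["a"]]), 4 * sqrt(f$vcov["rrm:a", "rrm:a"]))

  # constrained fit on data without PoO effects agrees with the
  # unconstrained fit's average origin effect
  ds <- simulate_dataset(sim_params(5000, 0, rr_mat = 1.5, rr_pat = 1.5,
                                    n_null_snps = 0, n_effect_snps = 1,
                                    seed = 31))
  g <- ds$geno
  fu <- fit_stratum(g$mother[, 1], g$father[, 1], g$child[, 1])
  fc <- fit_stratum(g$mother[, 1], g$father[, 1], g$child[, 1],
                    constrain_poo = TRUE)
  expect_true(fc$constrained)
  expect_equal(fc$log_rr_mat[["a"]],
               (fu$log_rr_mat[["a"]] + fu$log_rr_pat[["a"]]) / 2,
               tolerance = 0.05)
  expect_lt(abs(fc$log_rr_mat[["a"]] - log(1.5)),
            4 * sqrt(fc$vcov["rr:a", "rr:a"]))
  # the constraint cannot improve the likelihood
  expect_lte(fc$loglik, fu$loglik + 1e-8)

  expect_error(fit_stratum(rep(0, 50), rep(0, 50), rep(0, 50)),
               "monomorphic")
})

test_that("rare haplotypes are removed and multi-SNP fits stay coherent", {
  prm <- sim_params(800, 0, n_null_snps = 2, seed = 61)
  ds <- simulate_dataset(prm)
  g <- ds$geno
  fit <- fit_stratum(g$mother[, 1:2], g$father[, 1:2], g$child[, 1:2],
                     allele_ref = c("A", "A"), allele_var = c("C", "C"))
  expect_true(fit$converged)
  expect_equal(sum(fit$freq), 1, tolerance = 1e-10)
  expect_true(all(fit$freq >= 0.01 - 1e-6))
  # reference is the most frequent haplotype
  expect_equal(fit$reference, names(which.max(fit$freq)))
  # JSON serialization round-trips the key numbers
  f <- tempfile(fileext = ".json")
  write_stratum_fit(fit, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(unname(unlist(back$freq)), unname(fit$freq), tolerance = 1e-12)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-12)
})
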