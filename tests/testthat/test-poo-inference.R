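# Effect estimates and Wald tests: PoO, PoOxE, Child, GxE, and the scan.

# Minimal hand-built stratum fit for closed-form algebra checks.
fake_fit <- function(log_rrm, log_rrp, var_m, var_p, cov_mp = 0,
                     stratum = "x") {
  nm <- c("f:a", "rrm:a", "rrp:a")
  v <- diag(c(0.01, var_m, var_p))
  v[2, 3] <- v[3, 2] <- cov_mp
  dimnames(v) <- list(nm, nm)
  structure(list(freq = c(A = 0.8, a = 0.2),
                 log_rr_mat = c(a = log_rrm), log_rr_pat = c(a = log_rrp),
                 vcov = v, loglik = 0, n_families = 100L, n_skipped = 0L,
                 converged = TRUE, iterations = 1L, reference = "A",
                 hap_labels = c("A", "a"), constrained = FALSE,
                 stratum = stratum, method = "em"),
            class = "stratum_fit")
}

test_that("poo_effect computes RRR_PoO and its Wald interval", {
  f <- fake_fit(log(2), 0, 0.02, 0.02)
  po <- poo_effect(f)
  expect_equal(po$rrr_poo, 2, tolerance = 1e-12)
  se <- sqrt(0.04)
  expect_equal(po$se_log, se, tolerance = 1e-12)
  expect_equal(po$ci_low, exp(log(2) - qnorm(0.975) * se), tolerance = 1e-10)
  expect_equal(po$ci_high, exp(log(2) + qnorm(0.975) * se), tolerance = 1e-10)
  expect_equal(po$p_value, 2 * pnorm(-log(2) / se), tolerance = 1e-12)
  # CI bounds straddle the estimate and reproduce exp(log est +/- z se)
  expect_true(po$ci_low < po$rrr_poo && po$rrr_poo < po$ci_high)

  # covariance between origins enters the variance
  f2 <- fake_fit(log(2), 0, 0.02, 0.02, cov_mp = 0.01)
  expect_equal(poo_effect(f2)$se_log, sqrt(0.02 + 0.02 - 0.02),
               tolerance = 1e-12)

  # non-converged fits propagate as NA, not numbers
  fnc <- fake_fit(log(2), 0, 0.02, 0.02)
  fnc$converged <- FALSE
  expect_true(is.na(poo_effect(fnc)$p_value))
  expect_error(poo_effect(f, target = "zz"), "non-reference")
})

test_that("pooxe_test matches its closed-form normal algebra", {
  # equal PoO in both strata: interaction exactly 1, z = 0
  fe <- fake_fit(log(2), 0, 0.02, 0.02)
  fu <- fake_fit(log(2), 0, 0.02, 0.02)
  r <- pooxe_test(fe, fu)
  expect_equal(r$rrr_pooxe, 1, tolerance = 1e-12)
  expect_equal(r$wald_z, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  # log RRR_E = log 2 (se 0.2), log RRR_U = 0 (se 0.2)
  fe <- fake_fit(log(2), 0, 0.04, 0)
  fu <- fake_fit(0, 0, 0.04, 0)
  r <- pooxe_test(fe, fu)
  expect_equal(r$wald_z, log(2) / sqrt(0.08), tolerance = 1e-10)
  expect_equal(r$wald_z, 2.4507, tolerance = 1e-4)
  expect_equal(r$p_value, 0.0143, tolerance = 1e-2)

  # swapping the strata inverts the ratio and keeps the p-value
  r2 <- pooxe_test(fu, fe)
  expect_equal(r2$rrr_pooxe, 1 / r$rrr_pooxe, tolerance = 1e-12)
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-12)

  # mismatched haplotype spaces are a structural error
  fz <- fake_fit(0, 0, 0.04, 0)
  fz$hap_labels <- c("G", "g"); fz$reference <- "G"
  fz$log_rr_mat <- c(g = 0); fz$log_rr_pat <- c(g = 0)
  expect_error(pooxe_test(fe, fz), "different haplotype spaces")
})

test_that("child and GxE tests use the constrained model correctly", {
  ds <- simulate_dataset(sim_params(1500, 1500, variant_allele_freq = 0.3,
                                    rr_mat = 1.5, rr_pat = 1.5,
                                    n_null_snps = 0, n_effect_snps = 1,
                                    seed = 71))
  et <- effect_table(ds, "snp0001", "exposure")
  expect_equal(et$effect_type, c("Child", "GxE", "PoO", "PoOxE"))
  ch <- et[et$effect_type == "Child", ]
  expect_true(ch$ci_low < 1.5 && 1.5 < ch$ci_high)
  # no PoO and no interaction were simulated
  expect_gt(et$p_value[et$effect_type == "PoO"], 0.001)
  expect_gt(et$p_value[et$effect_type == "PoOxE"], 0.001)

  # GxE on identical strata parameters is exactly 1
  g <- ds$geno
  fc <- fit_stratum(g$mother[, 1], g$father[, 1], g$child[, 1],
                    constrain_poo = TRUE)
  cg <- child_and_gxe_tests(fc, fc, fc)
  expect_equal(cg$estimate[cg$effect_type == "GxE"], 1, tolerance = 1e-12)
  expect_equal(cg$estimate[cg$effect_type == "Child"],
               exp(fc$log_rr_mat[[1]]), tolerance = 1e-12)
  expect_error(child_and_gxe_tests(fake_fit(0, 0, 1, 1), fc, fc),
               "constrained")
})

test_that("the scan is deterministic, ranks true effects, and fails loudly", {
  prm <- sim_params(400, 200, variant_allele_freq = 0.2,
                    rr_mat = c(1, 3), n_null_snps = 8, n_effect_snps = 1,
                    seed = 99)
  ds <- simulate_dataset(prm)
  s1 <- scan_pooxe(ds, "exposure")
  s2 <- scan_pooxe(ds, "exposure")
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 9)
  expect_true(all(s1$converged))
  # effect SNP is the last column by construction
  eff <- ds$truth$effect_snps
  expect_lte(which(top_hits(s1, 9)$marker == eff), 3)

  # q-values attach to p-value rows only
  s1q <- add_q_values(s1)
  expect_false(anyNA(s1q$q_value))
  expect_true(all(diff(top_hits(s1q, 9)$q_value) >= -1e-12))

  # missing exposure families are dropped per scan
  ds$exposure$exposure[1:50] <- NA
  s3 <- scan_pooxe(ds, "exposure")
  expect_lt(s3$n_exposed[1] + s3$n_unexposed[1],
            s1$n_exposed[1] + s1$n_unexposed[1])

  ds$exposure$exposure[] <- NA
  expect_error(scan_pooxe(ds, "exposure"), "no observed values")
  expect_error(scan_pooxe(ds, "nope"), "not found")

  # a failing marker is reported, not fatal
  ds2 <- simulate_dataset(prm)
  ds2$geno$mother[, 2] <- 0L; ds2$geno$father[, 2] <- 0L
  ds2$geno$child[, 2] <- 0L
  s4 <- scan_pooxe(ds2, "exposure")
  expect_true(is.na(s4$p_value[s4$marker == "snp0002"]))
  expect_match(s4$note[s4$marker == "snp0002"], "monomorphic")
})

test_that("Wald and likelihood-ratio PoOxE tests agree asymptotically", {
  # test-side LR oracle: profile the shared PoO difference across strata
  lr_pvalue <- function(g, ex) {
    fe <- fit_stratum(g$mother[ex == 1, 1], g$father[ex == 1, 1],
                      g$child[ex == 1, 1])
    fu <- fit_stratum(g$mother[ex == 0, 1], g$father[ex == 0, 1],
                      g$child[ex == 0, 1])
    ll1 <- fe$loglik + fu$loglik
    nll0 <- function(th) {
      # th: (alr_fE, lrmE, alr_fU, lrmU, delta) with lrp = lrm - delta
      lle <- observed_data_loglik(
        g$mother[ex == 1, 1], g$father[ex == 1, 1], g$child[ex == 1, 1],
        c(1, exp(th[1])) / (1 + exp(th[1])),
        c(1, exp(th[2])), c(1, exp(th[2] - th[5])))
      llu <- observed_data_loglik(
        g$mother[ex == 0, 1], g$father[ex == 0, 1], g$child[ex == 0, 1],
        c(1, exp(th[3])) / (1 + exp(th[3])),
        c(1, exp(th[4])), c(1, exp(th[4] - th[5])))
      -(as.numeric(lle) + as.numeric(llu))
    }
    # under H0 the PoO difference delta is common; H0: delta free but equal
    # across strata vs H1: fully free (1 df)
    opt0 <- optim(c(0, 0, 0, 0, 0), nll0, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-12))
    lr <- 2 * (ll1 + opt0$value)
    pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }
  seeds <- rep_seeds(7000, 60)
  pw <- pl <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    ds <- simulate_dataset(sim_params(700, 350, rr_mat = c(1, 1.5),
                                      n_null_snps = 0, n_effect_snps = 1,
                                      seed = seeds[i]))
    g <- ds$geno; ex <- ds$truth$stratum
    fe <- fit_stratum(g$mother[ex == 1, 1], g$father[ex == 1, 1],
                      g$child[ex == 1, 1])
    fu <- fit_stratum(g$mother[ex == 0, 1], g$father[ex == 0, 1],
                      g$child[ex == 0, 1])
    pw[i] <- pooxe_test(fe, fu)$p_value
    pl[i] <- lr_pvalue(g, ex)
  }
  expect_gt(cor(pw, pl, method = "spearman"), 0.99)
})
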