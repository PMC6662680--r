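---
title: "Parent-of-origin by environment interaction analysis for case-parent triads"
author: "pooxe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-of-origin by environment interaction analysis for case-parent triads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pooxe)
```

## The question and the design

In a case-parent triad design an affected child and both biological parents
are genotyped; no external controls are needed. Beyond ordinary child
(fetal) genotype effects, this design can separate the risk conferred by an
allele inherited from the mother from the risk of the same allele inherited
from the father — a *parent-of-origin* (PoO) effect, the epidemiological
footprint of genomic imprinting. `pooxe` implements the next step: testing
whether the PoO effect itself differs between strata of a maternal
environmental exposure (smoking, alcohol, vitamin use), a PoO-by-environment
(PoOxE) interaction. The motivating application is genome-wide screening in
orofacial-cleft triad samples, where the real genotypes are
controlled-access; the package therefore ships a generative twin of the
fitted model so that every stage can be exercised against known truth.

The estimands, per variant (or haplotype) and exposure stratum:

* `RR_mat`, `RR_pat` — relative risk per maternally / paternally inherited
  copy of the target allele;
* `RRR_PoO = RR_mat / RR_pat` — the PoO effect;
* `RRR_PoOxE = RRR_PoO(exposed) / RRR_PoO(unexposed)` — the interaction.

All tests are two-sided Wald tests on the log scale; the null value of every
ratio is 1.

## The likelihood

Condition on the child being a case. The latent data for one family are the
four parental haplotypes: transmitted and untransmitted, maternal and
paternal, `(t_m, u_m, t_f, u_f)`. Under Hardy–Weinberg equilibrium, random
mating, a rare-disease multiplicative risk model with one multiplicative
relative risk per inherited non-reference haplotype, the latent-state
probability is

```
pi(t_m, u_m, t_f, u_f) = f(t_m) f(u_m) f(t_f) f(u_f) RR_mat(t_m) RR_pat(t_f) / Z
Z = (sum_h f(h) RR_mat(h)) * (sum_h f(h) RR_pat(h))
```

with `f` the haplotype frequencies. For a single diallelic SNP this reduces
to 16 states and `Z = (1 - p + p RR_mat)(1 - p + p RR_pat)`.

What is observed is less: unphased genotype dosages, possibly with the
father missing (a mother–child *dyad*). The observed-data likelihood of a
family is the sum of `pi` over all latent states compatible with its
genotypes — which marginalizes a missing parent and sums over haplotype
phase at once. Families compatible with no state (Mendelian errors that
survived QC) are skipped and counted, never silently absorbed.

### Estimation

`fit_stratum()` maximizes the observed-data log-likelihood per exposure
stratum over `(f, log RR_mat, log RR_pat)`. Two routes are provided and
agree (this is tested):

* **EM** (default). The key identity is the tilted-slot factorization:
  writing `g(h) = f(h) RR(h) / sum f RR`, the four latent slots are
  independent draws `t_m ~ g_m`, `u_m ~ f`, `t_f ~ g_f`, `u_f ~ f`. The
  M-step is therefore fully closed form: `f` is re-estimated from the
  expected untransmitted-slot counts, `g_m`/`g_f` from the transmitted
  slots, and `RR = (g/f)` renormalized to the reference haplotype. EM
  iterations never decrease the observed log-likelihood; convergence is
  declared when the improvement drops below `tol` (default `1e-8`).
* **BFGS** on the unconstrained scale (multinomial-logit frequencies,
  log relative risks).

The covariance is the inverse of the numerically differentiated observed
information at the optimum (`stats::optimHess`), on the same unconstrained
scale, so Wald intervals are symmetric in the log of each ratio.

Under the constraint `RR_mat = RR_pat` (used for child-effect and
gene–environment rows) the same EM applies with the two transmitted slots
pooled.

### Strata, and why standard errors add

Each family belongs to exactly one exposure stratum, and strata are fitted
fully separately — frequencies *and* risks. The interaction estimate is
then a contrast of independent quantities, so
`se(log RRR_PoOxE)^2 = se_E^2 + se_U^2`, and `z = log RRR_PoOxE / se`.
Families with missing exposure are dropped per exposure scan, not globally,
mirroring how study-description tables report per-exposure missing counts.

### Haplotypes

For 2–3 adjacent SNPs the haplotype space has 4 or 8 elements. An initial
frequency-only EM pass estimates the frequencies; haplotypes below
`frequency_floor` (default 1%) are then *removed from the space* and the
most frequent haplotype becomes the reference. We chose removal rather than
merging rare haplotypes into the reference class because merging is not
well defined for unphased likelihood contributions, and in practice the
haplotypes involved are the ones a stratified report would simply not show.
Families incompatible with the reduced space are dropped with a warning
count.

## Quality control

`run_qc()` applies, in order: call-rate (missing fraction > 5%), MAF
(< 5%), the exact conditional Hardy–Weinberg test (p < 0.001; the test
fixes the minor-allele total and enumerates heterozygote counts of the same
parity), Mendelian-error rate (> 1%), and finally perfect-LD pruning
(`r^2 = 1` within a 5-SNP flanking window, later SNP dropped) on the
survivors. Criteria are counted independently — a SNP can fail several —
but each SNP is removed once. Allele-frequency-based metrics use parents
only: the children are ascertained cases and not independent of their
parents. The Mendel threshold default is 1%, matching the tabulated
criterion in the motivating study (its Methods prose says 10%, which is
inconsistent with its own table; the threshold is a configurable knob).
After filtering, families with a Mendelian-inconsistent triple at a
retained SNP have that SNP blanked for that family, the standard practice
when the offending member cannot be identified.

## False discovery rates

`estimate_pi0()` and `q_values()` implement the Storey–Tibshirani
procedure: `pi0(lambda) = #{p > lambda} / (m (1 - lambda))` on
`lambda = 0, 0.05, ..., 0.90`, a 3-df smoothing spline through those
points evaluated at the largest lambda, clipped to (0, 1]; then the
step-down `q_(i) = min(pi0 m p_(i) / i, q_(i+1))`. With `pi0 = 1` the
q-values are exactly Benjamini–Hochberg adjusted p-values, which the tests
verify against an independent implementation. Below 100 p-values the spline
is unreliable and the conservative `pi0 = 1` is used. `qq_data()` returns
QQ-plot coordinates with pointwise bands from the `Beta(i, m-i+1)` order
statistic distributions; note these are pointwise bands — each point falls
inside with 95% probability, but neighboring order statistics are strongly
correlated, so a single realization can show long runs outside the band
without indicating miscalibration.

## Power

`asymptotic_power()` computes the expected per-family Fisher information of
the *observable*-genotype multinomial (the 15 triad cells over
mother/father/child dosages; dyad cells with the father marginalized,
mixed in proportion to `dyad_fraction`) at the true parameters, on the
estimation scale. The asymptotic variance of `log RRR_PoOxE` is
`v_E/n_E + v_U/n_U` and power of the two-sided level-`alpha` Wald test is
`pnorm(delta - z) + pnorm(-delta - z)` with `delta = |log RRR_PoOxE|/se`.
Using observable rather than complete-data information matters: it is what
the Wald test actually has, and it makes dyads correctly reduce power. At
the null the formula returns exactly `alpha`. Power curves follow the
convention of varying only the maternal RR in exposed triads, so the
abscissa `RRR` equals `RR_mat(exposed)`; the default design is 1100
unexposed and 500 exposed triads at MAF 0.2 with `alpha = 0.05`.

## The synthetic-data generator

`simulate_dataset()` draws families i.i.d. within stratum from the exact
latent-state distribution above and collapses to observed dosages
(`M = t_m + u_m`, `F = t_f + u_f`, `C = t_m + t_f`). Its fixed design
choices:

* exposure is a family-level design variable with exact stratum sizes
  (defaults 1100 unexposed / 500 exposed, the reference power design), so
  calibration experiments have exact n per stratum;
* fathers go missing completely at random with `dyad_fraction`; exposure
  records likewise — no informative missingness;
* one child per family; SNPs are mutually independent (no LD is
  simulated); autosomal inheritance only;
* `inject_errors()` flips single alleles of genotype calls at a given rate
  to create the Mendelian inconsistencies and HWE departures the QC
  filters look for.

Because the generator is the model's exact generative twin, passing
calibration tests demonstrates internal consistency of estimator, test and
power formula — it does not demonstrate robustness to features real data
have and the generator lacks: population stratification, LD, genotyping
error structure beyond random flips, informative missingness, multiple
offspring per family, or X-linked loci.

## Numerical choices and degenerate inputs

* EM tolerance `1e-8` on the log-likelihood improvement, at most 5000
  iterations; non-convergence is a flag on the fit, propagated as `NA`
  results, never silent numbers.
* Expected slot counts are floored at `1e-12` in the M-step so boundary
  estimates cannot produce `NaN`; monomorphic loci are a hard error
  (risks are not estimable).
* Frequencies are optimized on the multinomial-logit scale, risks on the
  natural log scale; ties for the reference haplotype break toward the
  lower haplotype index.
* p-values of exactly 0 are floored at `1e-300` before `-log10` in QQ
  data; an all-null `pi0` estimate below 0 is clipped with a warning.
* The covariance solve can fail on degenerate data; the fit then carries
  an `NA` covariance and a warning rather than fabricated standard errors.

## Problem sizes used in validation

The shipped test-suite and acceptance script validate at the reference
design (MAF 0.2, 1100/500 triads): 2000 global-null replicates for type-I
error, 1000 replicates per setting for CI coverage at true
`RRR_PoOxE` in {1, 2, 3.67}, 1000 replicates of a 10,000-marker p-value mix
for FDR calibration, 400 Monte-Carlo datasets per cell of a 3-by-3
(effect size, sample size) power grid, and 60 replicates of a 201-SNP scan
with one true interaction of size 3.67 (a magnitude reported for a cleft
candidate locus) for ranking behavior. The exact HWE test is compared to
full enumeration at every configuration up to 200 individuals. These sizes
give Monte-Carlo standard errors comfortably below the tolerances asserted.

## Known limitations

* No maternal-genotype effects, no covariate adjustment, no X chromosome,
  no imputation of untyped SNPs, no relatedness/sample-level QC.
* Both-parents-missing families are excluded rather than modeled.
* The constrained (child/GxE) and unconstrained fits use stratum-specific
  haplotype frequencies; a shared-frequency mode is deliberately out of
  scope.
* Asymptotic power covers single SNPs; haplotype-level power is not
  implemented.
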