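# Asymptotic power of the Wald PoOxE test, from the expected Fisher
# information of the observable-genotype multinomial in each stratum.

#' Specify a design for a PoOxE power calculation
#'
#' @param n_unexposed,n_exposed Number of families per stratum.
#' @param maf Variant (minor) allele frequency, strictly in (0, 1).
#' @param rr_mat_exposed,rr_pat_exposed,rr_mat_unexposed,rr_pat_unexposed
#'   True per-origin relative risks in each stratum; the implied interaction
#'   is `RRR_PoOxE = (rr_mat_E / rr_pat_E) / (rr_mat_U / rr_pat_U)`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param dyad_fraction Fraction of families with the father ungenotyped
#'   (default 0: complete triads, the setting used for power curves).
#' @return An object of class `power_design`.
#' @export
power_design <- function(n_unexposed = 1100, n_exposed = 500, maf = 0.2,
                         rr_mat_exposed = 1, rr_pat_exposed = 1,
                         rr_mat_unexposed = 1, rr_pat_unexposed = 1,
                         alpha = 0.05, dyad_fraction = 0) {
  if (maf <= 0 || maf >= 1) stop("maf must lie strictly in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  rr <- c(rr_mat_exposed, rr_pat_exposed, rr_mat_unexposed, rr_pat_unexposed)
  if (any(rr <= 0)) stop("relative risks must be strictly positive")
  if (dyad_fraction < 0 || dyad_fraction > 1)
    stop("dyad_fraction must lie in [0, 1]")
  if (n_unexposed < 1 || n_exposed < 1)
    stop("both strata need at least one family")
  out <- list(n_unexposed = n_unexposed, n_exposed = n_exposed, maf = maf,
              rr_mat_exposed = rr_mat_exposed, rr_pat_exposed = rr_pat_exposed,
              rr_mat_unexposed = rr_mat_unexposed,
              rr_pat_unexposed = rr_pat_unexposed,
              alpha = alpha, dyad_fraction = dyad_fraction)
  class(out) <- "power_design"
  out
}

#' @export
print.power_design <- function(x, ...) {
  rrr <- (x$rr_mat_exposed / x$rr_pat_exposed) /
    (x$rr_mat_unexposed / x$rr_pat_unexposed)
  cat(sprintf("PoOxE power design: %g unexposed + %g exposed families, MAF %.3g\n",
              x$n_unexposed, x$n_exposed, x$maf))
  cat(sprintf("  true RRR_PoOxE = %.3g, alpha = %g, dyad fraction %.3g\n",
              rrr, x$alpha, x$dyad_fraction))
  cat(sprintf("  asymptotic power: %.4f\n", asymptotic_power(x)))
  invisible(x)
}

# Probabilities of the observable genotype categories in one stratum.
# type = "triad": cells over (M, F, C); type = "dyad": cells over (M, C)
# with the father marginalized out.
observable_cell_probs <- function(p, rr_mat, rr_pat, type = c("triad", "dyad")) {
  type <- match.arg(type)
  st <- state_index(2L)
  freq <- c(1 - p, p)
  pi <- state_probs(freq, c(1, rr_mat), c(1, rr_pat), st)
  M <- (st$tm - 1L) + (st$um - 1L)
  F_ <- (st$tf - 1L) + (st$uf - 1L)
  C <- (st$tm - 1L) + (st$tf - 1L)
  key <- if (type == "triad") paste(M, F_, C) else paste(M, C)
  as.vector(rowsum(pi, key))
}

# Expected per-family Fisher information on the estimation scale
# theta = (logit p, log rr_mat, log rr_pat), from the multinomial over
# observable categories: I = sum_k grad P_k grad P_k' / P_k
# (multinomial identity; gradients by central differences).
stratum_information <- function(p, rr_mat, rr_pat, dyad_fraction = 0) {
  theta <- c(stats::qlogis(p), log(rr_mat), log(rr_pat))
  info_for <- function(type) {
    cells <- function(th)
      observable_cell_probs(stats::plogis(th[1]), exp(th[2]), exp(th[3]), type)
    P <- cells(theta)
    h <- 1e-5
    G <- vapply(1:3, function(j) {
      tp <- tm <- theta
      tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      (cells(tp) - cells(tm)) / (2 * h)
    }, numeric(length(P)))
    keep <- P > 1e-14
    crossprod(G[keep, , drop = FALSE] / sqrt(P[keep]))
  }
  I <- (1 - dyad_fraction) * info_for("triad")
  if (dyad_fraction > 0) I <- I + dyad_fraction * info_for("dyad")
  I
}

# Asymptotic per-family variance of log RRR_PoO in one stratum.
poo_asymptotic_var <- function(p, rr_mat, rr_pat, dyad_fraction = 0) {
  I <- stratum_information(p, rr_mat, rr_pat, dyad_fraction)
  cvec <- c(0, 1, -1)
  drop(t(cvec) %*% solve(I) %*% cvec)
}

#' Asymptotic power of the Wald PoOxE test
#'
#' Computes, for each stratum, the expected per-family Fisher information of
#' the observable genotype multinomial at the true parameters (triad cells
#' over mother/father/child dosages; dyad cells with the father
#' marginalized, weighted by `dyad_fraction`). The asymptotic variance of
#' `log RRR_PoOxE` is `v_E / n_E + v_U / n_U`, and power of the two-sided
#' level-`alpha` Wald test is
#' `pnorm(delta - z) + pnorm(-delta - z)` with
#' `delta = |log RRR_PoOxE| / se` and `z = qnorm(1 - alpha/2)`.
#' At `RRR_PoOxE = 1` this equals `alpha` exactly.
#'
#' @param design A [power_design()].
#' @return The power, a probability.
#' @examples
#' asymptotic_power(power_design(rr_mat_exposed = 2))
#' @export
asymptotic_power <- function(design) {
  stopifnot(inherits(design, "power_design"))
  v_e <- poo_asymptotic_var(design$maf, design$rr_mat_exposed,
                            design$rr_pat_exposed, design$dyad_fraction)
  v_u <- poo_asymptotic_var(design$maf, design$rr_mat_unexposed,
                            design$rr_pat_unexposed, design$dyad_fraction)
  log_rrr <- (log(design$rr_mat_exposed) - log(design$rr_pat_exposed)) -
    (log(design$rr_mat_unexposed) - log(design$rr_pat_unexposed))
  se <- sqrt(v_e / design$n_exposed + v_u / design$n_unexposed)
  delta <- abs(log_rrr) / se
  z <- stats::qnorm(1 - design$alpha / 2)
  stats::pnorm(delta - z) + stats::pnorm(-delta - z)
}

#' Power curves over a grid of interaction sizes, MAFs or sample sizes
#'
#' Varies one design axis at a time, in the convention of the reference
#' power analysis: the `rrr` grid moves the maternal relative risk in the
#' exposed stratum so that `RRR_PoOxE = rr_mat(exposed)` with all other
#' relative risks 1.
#'
#' @param design A [power_design()] template.
#' @param rrr_grid Interaction sizes (sets `rr_mat_exposed`).
#' @param maf_grid Minor allele frequencies.
#' @param n_grid Total family counts; the template's exposed:unexposed split
#'   is preserved.
#' @return A data frame with columns `axis`, `value`, `power`.
#' @export
power_curve <- function(design, rrr_grid = NULL, maf_grid = NULL,
                        n_grid = NULL) {
  stopifnot(inherits(design, "power_design"))
  grids <- list(rrr = rrr_grid, maf = maf_grid, n = n_grid)
  grids <- grids[!vapply(grids, is.null, logical(1))]
  if (!length(grids)) stop("provide at least one non-empty grid")
  rows <- list()
  for (axis in names(grids)) {
    for (v in grids[[axis]]) {
      d <- design
      if (axis == "rrr") {
        d$rr_mat_exposed <- v
        d$rr_pat_exposed <- d$rr_mat_unexposed <- d$rr_pat_unexposed <- 1
      } else if (axis == "maf") {
        d$maf <- v
      } else {
        frac_e <- design$n_exposed / (design$n_exposed + design$n_unexposed)
        d$n_exposed <- v * frac_e
        d$n_unexposed <- v * (1 - frac_e)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, value = v, power = asymptotic_power(d),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
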