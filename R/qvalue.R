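# Storey-Tibshirani false discovery rates: spline pi0 estimate, step-down
# q-values, and QQ-plot data with beta order-statistic bands.

#' Estimate the proportion of true null hypotheses (pi0)
#'
#' The spline estimator: `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`
#' over the tuning grid, a cubic smoothing spline (3 df) through the
#' `(lambda, pi0(lambda))` points, evaluated at the largest lambda and
#' clipped to (0, 1]. With fewer than 100 p-values the spline is unreliable
#' and the conservative `pi0 = 1` is returned with a message.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @param lambda_grid Tuning grid (default `seq(0, 0.90, 0.05)`).
#' @return An object of class `pi0_estimate`: a list with `pi0`,
#'   `lambda_grid`, `pi0_lambda` and `m`.
#' @export
estimate_pi0 <- function(p_values, lambda_grid = seq(0, 0.90, by = 0.05)) {
  p <- p_values
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  lambda_grid <- sort(lambda_grid)
  if (m < 100L) {
    message("fewer than 100 p-values: using conservative pi0 = 1")
    out <- list(pi0 = 1, lambda_grid = lambda_grid,
                pi0_lambda = rep(NA_real_, length(lambda_grid)), m = m)
    class(out) <- "pi0_estimate"
    return(out)
  }
  pi0_lam <- vapply(lambda_grid,
                    function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda_grid, pi0_lam, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda_grid))$y
  if (pi0 > 1) pi0 <- 1
  if (pi0 <= 0) {
    warning("pi0 estimate non-positive; clipped to 1/m")
    pi0 <- 1 / m
  }
  out <- list(pi0 = pi0, lambda_grid = lambda_grid, pi0_lambda = pi0_lam,
              m = m)
  class(out) <- "pi0_estimate"
  out
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat(sprintf("pi0 = %.4f (spline over %d lambda values, m = %d tests)\n",
              x$pi0, length(x$lambda_grid), x$m))
  invisible(x)
}

#' Storey-Tibshirani q-values
#'
#' For ordered p-values `p_(1) <= ... <= p_(m)`:
#' `q_(m) = pi0 * p_(m)` and `q_(i) = min(pi0 * m * p_(i) / i, q_(i+1))`,
#' returned in the input order. A marker's q-value is the minimum FDR at
#' which it would be called significant; calling all markers with q < 0.2
#' targets a false discovery rate of 20%.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @param pi0 Proportion of true nulls; a number, a `pi0_estimate`, or
#'   `NULL` (default) to estimate it with [estimate_pi0()]. With `pi0 = 1`
#'   the q-values are exactly the Benjamini-Hochberg adjusted p-values.
#' @return Numeric vector of q-values aligned to `p_values`, with the pi0
#'   used attached as attribute `"pi0"`.
#' @examples
#' q_values(c(0.1, 0.2, 0.3, 0.4), pi0 = 1)  # all 0.4
#' @export
q_values <- function(p_values, pi0 = NULL) {
  p <- p_values
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(pi0)) pi0 <- estimate_pi0(p)
  if (inherits(pi0, "pi0_estimate")) pi0 <- pi0$pi0
  stopifnot(is.numeric(pi0), length(pi0) == 1L, pi0 > 0, pi0 <= 1)
  m <- length(p)
  o <- order(p)
  q_ord <- pi0 * m * p[o] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q <- numeric(m)
  q[o] <- pmin(q_ord, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Fill in q-values on a scan result
#'
#' @param scan A `pooxe_scan` data frame (or any data frame with a
#'   `p_value` column and a `q_value` column to fill).
#' @param pi0 Passed to [q_values()]; `NULL` estimates it from the scan's
#'   non-missing p-values.
#' @return The scan with `q_value` filled for rows that produced a p-value;
#'   markers without a p-value stay `NA` and do not count toward m.
#' @export
add_q_values <- function(scan, pi0 = NULL) {
  ok <- !is.na(scan$p_value)
  if (!any(ok)) return(scan)
  scan$q_value[ok] <- as.numeric(q_values(scan$p_value[ok], pi0))
  scan
}

#' Data for a QQ plot of p-values with pointwise confidence bands
#'
#' Expected quantiles are the medians of the uniform order statistics
#' (`qbeta(0.5, i, m - i + 1)`), and the pointwise band at `band_level`
#' comes from the same Beta order-statistic distributions; everything is
#' returned on the `-log10` scale, observed p-values sorted ascending.
#'
#' @param p_values Vector of p-values.
#' @param band_level Pointwise band level (default 0.95).
#' @param p_floor P-values below this are capped before `-log10`
#'   (default 1e-300).
#' @return A data frame with columns `expected`, `observed`, `band_lo`,
#'   `band_hi` (all `-log10` scale), one row per p-value, sorted so both
#'   axes are non-decreasing.
#' @export
qq_data <- function(p_values, band_level = 0.95, p_floor = 1e-300) {
  p <- p_values
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m < 1L) stop("at least one p-value is required")
  if (any(p < p_floor)) {
    message(sprintf("%d p-value(s) below %g capped for the -log10 scale",
                    sum(p < p_floor), p_floor))
    p <- pmax(p, p_floor)
  }
  i <- seq_len(m)
  a <- (1 - band_level) / 2
  out <- data.frame(
    expected = -log10(stats::qbeta(0.5, i, m - i + 1)),
    observed = -log10(sort(p)),
    band_lo = -log10(stats::qbeta(1 - a, i, m - i + 1)),
    band_hi = -log10(stats::qbeta(a, i, m - i + 1))
  )
  out <- out[order(out$expected), ]
  rownames(out) <- NULL
  attr(out, "band") <- sprintf("pointwise %g%% band from Beta(i, m-i+1) order statistics",
                               100 * band_level)
  out
}
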