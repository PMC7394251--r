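#' Pearson correlation between the two methods
#'
#' @param data A data frame of paired measurements.
#' @param reference,test Columns holding the two methods' values (unquoted).
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_correlation <- function(data, reference = NULL, test = NULL) {
  xy <- extract_xy(data, {{ reference }}, {{ test }})
  if (length(xy$x) < 3) {
    ab_abort("Pearson correlation requires at least 3 pairs.",
             "assaybias_insufficient_data")
  }
  if (var(xy$x) == 0 || var(xy$y) == 0) {
    ab_abort("Correlation undefined: one of the methods has zero variance.",
             "assaybias_singular_fit")
  }
  cor(xy$x, xy$y)
}

#' Anderson-Darling test of normality
#'
#' Composite-null Anderson-Darling test (mean and variance estimated from
#' the sample), as implemented in [nortest::ad.test()]: the reported
#' statistic is A2; the p-value applies the small-sample correction
#' `A2* = A2 (1 + 0.75/n + 2.25/n^2)` before the standard piecewise
#' approximation. Used here on standardized regression residuals to judge
#' whether regression-based conclusions are trustworthy.
#'
#' @param x Numeric vector, `n >= 8`.
#' @return A tibble with `statistic` (A2) and `p.value`.
#' @export
ad_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8) {
    ab_abort("Anderson-Darling normality test requires n >= 8.",
             "assaybias_insufficient_data")
  }
  t <- nortest::ad.test(x)
  tibble::tibble(statistic = unname(t$statistic), p.value = t$p.value)
}

# Kolmogorov tail: P(sup|bridge| > stat) = 2 sum_{k>=1} (-1)^(k-1) exp(-2 k^2 stat^2)
.kolmogorov_p <- function(stat) {
  if (stat <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * stat^2))
  min(max(p, 0), 1)
}

# bridge-corrected sign-cusum statistic: residual signs ordered by xhat,
# cumulated, tied down at both ends, scaled by sqrt(n_eff)
.cusum_stat <- function(residuals, xhat) {
  ord <- order(xhat)  # stable: ties keep input order
  s <- sign(residuals[ord])
  s <- s[s != 0]
  n_eff <- length(s)
  if (n_eff == 0) return(list(stat = 0, n_eff = 0L, one_signed = FALSE))
  one_signed <- all(s > 0) || all(s < 0)
  cs <- cumsum(s)
  cs <- cs - seq_len(n_eff) / n_eff * cs[n_eff]
  list(stat = max(abs(cs)) / sqrt(n_eff), n_eff = n_eff,
       one_signed = one_signed)
}

#' CUSUM test of linearity for a Deming fit
#'
#' Orders the residual signs by estimated true concentration (ties broken
#' by input order) and cumulates them; a run of same-signed residuals over
#' a stretch of the concentration axis — the fingerprint of a nonlinear
#' relationship — drives the cumulative sum away from zero. The statistic
#' is the bridge-corrected excursion `max_k |cusum_k - (k/n) cusum_n| /
#' sqrt(n_eff)` (zero residuals dropped; `n_eff` the number of nonzero
#' signs), tied down at both ends so that the overall sign imbalance does
#' not masquerade as a trend.
#'
#' Because the residuals come from a fitted two-parameter line, their
#' signs are not exchangeable: the fit absorbs part of any excursion, and
#' referring the statistic to a random-walk (Kolmogorov) tail makes the
#' test noticeably conservative at study sizes around n = 50. The default
#' p-value is therefore a parametric-bootstrap one: noise is redrawn from
#' the fitted heteroscedastic model (normal, variance `1/w_i`), projected
#' through the weighted least-squares hat matrix of the fitted line — so
#' each bootstrap residual vector carries exactly the dependence a fitted
#' line induces — and the statistic's null distribution is accumulated
#' over `n_boot` draws with a fixed internal seed, making the p-value
#' deterministic. `method = "asymptotic"` gives the Kolmogorov tail
#' instead.
#'
#' @param fit A [deming_fit()] (residuals, weights and `xhat` are taken
#'   from it), with at least 10 samples.
#' @param method `"bootstrap"` (default) or `"asymptotic"`.
#' @param n_boot Bootstrap draws (default 1000).
#' @return A tibble with `statistic` and `p.value`.
#' @export
cusum_linearity <- function(fit, method = c("bootstrap", "asymptotic"),
                            n_boot = 1000) {
  stopifnot(inherits(fit, "deming_fit"))
  method <- match.arg(method)
  if (fit$n < 10) {
    ab_abort("CUSUM linearity test requires at least 10 samples.",
             "assaybias_insufficient_data")
  }
  obs <- .cusum_stat(fit$residuals, fit$xhat)
  if (obs$n_eff == 0) {
    warn("All residuals are exactly zero; linearity test degenerate.")
    return(tibble::tibble(statistic = 0, p.value = 1))
  }
  if (obs$one_signed) {
    warn("All residuals share one sign; the fit is pathological and the linearity statistic is maximal.")
    return(tibble::tibble(statistic = sqrt(obs$n_eff), p.value = 0))
  }
  p <- if (method == "asymptotic") {
    .kolmogorov_p(obs$stat)
  } else {
    n <- fit$n
    X <- cbind(1, fit$x)
    w <- fit$weights
    XtW <- t(X * w)
    A <- solve(XtW %*% X, XtW)  # 2 x n projection coefficients
    sdv <- 1 / sqrt(w)
    null_stats <- withr::with_seed(987654321L, {
      E <- matrix(rnorm(n * n_boot), nrow = n) * sdv
      R <- E - X %*% (A %*% E)  # residuals of the fitted line under the null
      vapply(seq_len(n_boot), function(b) {
        .cusum_stat(R[, b], fit$xhat)$stat
      }, numeric(1))
    })
    (1 + sum(null_stats >= obs$stat - 1e-12)) / (n_boot + 1)
  }
  tibble::tibble(statistic = obs$stat, p.value = p)
}

#' Regression-suitability diagnostics for a Deming fit
#'
#' Bundles the three checks used to decide whether a regression-based
#' method comparison can be trusted: the Pearson correlation between the
#' two methods, an Anderson-Darling test of normality of the standardized
#' residuals, and a CUSUM test of linearity. A significant normality or
#' linearity test (p < `alpha`) flags the regression assumptions as
#' suspect; it does not by itself invalidate the bias estimates.
#'
#' @param fit A [deming_fit()].
#' @param alpha Significance level for the flags (default 0.05).
#' @param cusum_method,n_boot Passed to [cusum_linearity()].
#' @return A one-row tibble: `pearson_r`, `normality_stat`, `normality_p`,
#'   `linearity_stat`, `linearity_p`, `alpha`, `normality_ok`,
#'   `linearity_ok`.
#' @export
regression_diagnostics <- function(fit, alpha = 0.05,
                                   cusum_method = c("bootstrap", "asymptotic"),
                                   n_boot = 1000) {
  stopifnot(inherits(fit, "deming_fit"))
  ad <- ad_normality(fit$std_residuals)
  cu <- cusum_linearity(fit, method = match.arg(cusum_method),
                        n_boot = n_boot)
  tibble::tibble(
    pearson_r = cor(fit$x, fit$y),
    normality_stat = ad$statistic, normality_p = ad$p.value,
    linearity_stat = cu$statistic, linearity_p = cu$p.value,
    alpha = alpha,
    normality_ok = ad$p.value >= alpha,
    linearity_ok = cu$p.value >= alpha
  )
}
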