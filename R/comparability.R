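#' Comparability verdict for a test method against the reference
#'
#' Applies the two CLSI EP09-style acceptance approaches side by side:
#'
#' * **Regression criteria** — the 95% confidence intervals of the Deming
#'   slope and intercept must contain 1 and 0, respectively. The headline
#'   `comparable` flag is their conjunction.
#' * **Bias criterion** — the mean relative bias must lie within
#'   `+/- rb_tolerance_pct` (default 20%, matching an 80–120% recovery
#'   acceptance band). Tracked separately in `mean_rb_within_tol`; it does
#'   not enter `comparable`.
#'
#' Diagnostics failures (non-normal residuals or nonlinearity at `alpha`)
#' do not veto the verdict but are surfaced in `notes`, signalling that
#' regression-based conclusions need caution.
#'
#' @param fit A [deming_fit()] with jack-knife confidence intervals.
#' @param bias A [bias_summary()] computed on the same dataset.
#' @param diagnostics Optional [regression_diagnostics()] row for the same
#'   fit.
#' @param rb_tolerance_pct Acceptance band for the mean relative bias, in
#'   percent (default 20).
#' @param alpha Significance level for diagnostic notes (default 0.05).
#' @return A one-row tibble of class `comparability_verdict`:
#'   `slope_ci_contains_1`, `intercept_ci_contains_0`, `comparable`,
#'   `mean_rb_within_tol`, `rb_tolerance_pct`, `diagnostics_ok`, `notes`
#'   (list-column of character warnings).
#' @examples
#' d <- paired_dataset(exp(rnorm(30)), exp(rnorm(30, 0.02, 1)))
#' @export
evaluate_comparability <- function(fit, bias, diagnostics = NULL,
                                   rb_tolerance_pct = 20, alpha = 0.05) {
  stopifnot(inherits(fit, "deming_fit"), inherits(bias, "bias_summary"))
  if (anyNA(fit$slope_ci) || anyNA(fit$intercept_ci)) {
    ab_abort("The fit has no confidence intervals; run `jackknife_ci()` before evaluating comparability.",
             "assaybias_config_error")
  }
  slope_ok <- fit$slope_ci[1] <= 1 && 1 <= fit$slope_ci[2]
  int_ok <- fit$intercept_ci[1] <= 0 && 0 <= fit$intercept_ci[2]
  rb_ok <- abs(bias$mean_rb) <= rb_tolerance_pct
  notes <- character(0)
  diag_ok <- NA
  if (!is.null(diagnostics)) {
    diag_ok <- isTRUE(diagnostics$normality_p >= alpha) &&
      isTRUE(diagnostics$linearity_p >= alpha)
    if (isTRUE(diagnostics$normality_p < alpha)) {
      notes <- c(notes, sprintf(
        "standardized residuals depart from normality (Anderson-Darling p = %.3g); interpret regression criteria with caution",
        diagnostics$normality_p))
    }
    if (isTRUE(diagnostics$linearity_p < alpha)) {
      notes <- c(notes, sprintf(
        "CUSUM test indicates nonlinearity (p = %.3g); a single slope/intercept may not describe the relationship",
        diagnostics$linearity_p))
    }
  }
  if (!rb_ok) {
    notes <- c(notes, sprintf(
      "mean relative bias %.1f%% exceeds the +/-%g%% acceptance band",
      bias$mean_rb, rb_tolerance_pct))
  }
  out <- tibble::tibble(
    slope_ci_contains_1 = slope_ok,
    intercept_ci_contains_0 = int_ok,
    comparable = slope_ok && int_ok,
    mean_rb_within_tol = rb_ok,
    rb_tolerance_pct = rb_tolerance_pct,
    diagnostics_ok = diag_ok,
    notes = list(notes)
  )
  class(out) <- c("comparability_verdict", class(out))
  out
}
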