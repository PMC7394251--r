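#' Relative bias of a test-method result against a reference result
#'
#' The per-sample relative bias, in percent:
#' \deqn{RB = 100\,(C_{test} - C_{ref})/C_{ref}.}
#'
#' @param c_test Test-method concentration(s).
#' @param c_ref Reference-method concentration(s), strictly positive.
#' @return Relative bias in percent (vectorized).
#' @examples
#' relative_bias(2, 1)    # +100
#' relative_bias(0.69, 1) # -31
#' @export
relative_bias <- function(c_test, c_ref) {
  if (any(!is.finite(c_ref)) || any(c_ref <= 0)) {
    ab_abort("Relative bias is undefined for non-positive reference concentrations.",
             "assaybias_positivity_error")
  }
  100 * (c_test - c_ref) / c_ref
}

#' Per-sample and summary bias statistics with Bland-Altman limits
#'
#' Computes, for each paired sample, the absolute bias `AB = test -
#' reference` (concentration units) and the relative bias `RB` (percent),
#' then summarizes them: mean AB, mean RB, the CV% of RB
#' (`100 * sd(RB)/|mean(RB)|`), and Bland-Altman statistics (mean
#' difference and 95% limits of agreement `mean(AB) +/- 1.96 sd(AB)`).
#'
#' @param data A data frame of paired measurements (see [paired_dataset()]).
#' @param reference,test Columns holding the two methods' concentrations
#'   (unquoted); default to `reference` and `test`.
#' @param ba_axis Abscissa convention for the Bland-Altman view:
#'   `"reference"` (default; differences plotted against the
#'   reference-method value, treating it as comparative truth) or `"mean"`
#'   (classical mean-of-methods axis).
#' @return A `bias_summary` object. `tidy()` returns the per-sample tibble
#'   (`sample`, `reference`, `test`, `ab`, `rb`, `ba_x`); `glance()` the
#'   one-row summary (`n`, `mean_ab`, `mean_rb`, `rb_cv_pct`,
#'   `ba_mean_diff`, `ba_loa_low`, `ba_loa_high`).
#' @examples
#' d <- paired_dataset(c(1, 2, 4), c(1.5, 3, 6))
#' glance(bias_summary(d))  # mean RB +50%, CV 0
#' @export
bias_summary <- function(data, reference = NULL, test = NULL,
                         ba_axis = c("reference", "mean")) {
  ba_axis <- match.arg(ba_axis)
  xy <- extract_xy(data, {{ reference }}, {{ test }})
  x <- xy$x
  y <- xy$y
  validate_paired_data(tibble::tibble(reference = x, test = y), min_n = 2)
  ab <- y - x
  rb <- relative_bias(y, x)
  n <- length(x)
  mean_ab <- mean(ab)
  mean_rb <- mean(rb)
  sd_ab <- sd(ab)
  # |mean| in the denominator so negatively biased assays get a positive CV%
  rb_cv_pct <- if (mean_rb == 0) NA_real_ else 100 * sd(rb) / abs(mean_rb)
  structure(
    list(
      samples = tibble::tibble(
        sample = if ("sample_id" %in% names(data)) data$sample_id else
          paste0("S", seq_len(n)),
        reference = x, test = y, ab = ab, rb = rb,
        ba_x = if (ba_axis == "reference") x else (x + y) / 2
      ),
      n = n, mean_ab = mean_ab, mean_rb = mean_rb, rb_cv_pct = rb_cv_pct,
      ba_mean_diff = mean_ab,
      ba_loa_low = mean_ab - 1.96 * sd_ab,
      ba_loa_high = mean_ab + 1.96 * sd_ab,
      ba_axis = ba_axis,
      analyte = if ("analyte" %in% names(data)) data$analyte[1] else NA_character_,
      unit = if ("unit" %in% names(data)) data$unit[1] else NA_character_
    ),
    class = "bias_summary"
  )
}

#' @export
print.bias_summary <- function(x, ...) {
  cat("Bias summary (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  mean AB: %.4g    mean RB: %.2f%% (CV %.2f%%)\n",
              x$mean_ab, x$mean_rb, x$rb_cv_pct))
  cat(sprintf("  Bland-Altman: %.4g [%.4g, %.4g]\n",
              x$ba_mean_diff, x$ba_loa_low, x$ba_loa_high))
  invisible(x)
}

#' @export
tidy.bias_summary <- function(x, ...) x$samples

#' @export
glance.bias_summary <- function(x, ...) {
  tibble::tibble(
    n = x$n, mean_ab = x$mean_ab, mean_rb = x$mean_rb,
    rb_cv_pct = x$rb_cv_pct, ba_mean_diff = x$ba_mean_diff,
    ba_loa_low = x$ba_loa_low, ba_loa_high = x$ba_loa_high
  )
}

# ---- proportional-bias curve -------------------------------------------------

#' Proportional-bias curve along the concentration axis
#'
#' From a fitted regression line, the regression-predicted percent
#' deviation from identity at concentration C:
#' \deqn{PB(C) = 100\,\frac{(b - 1)C + a}{C} = 100\,(b - 1 + a/C),}
#' with slope b and intercept a. The intercept term dominates at low
#' concentrations — the signature of additive cross-reactivity
#' interference — while \eqn{PB \to 100(b-1)} as C grows. Pointwise 95%
#' confidence bands are jack-knifed from the fit's leave-one-out estimates:
#' at each grid point the SE of the leave-one-out PB values is combined
#' with a t quantile on `n - 2` degrees of freedom.
#'
#' @param fit A [deming_fit()] with jack-knife results (`loo` populated).
#' @param grid Concentrations at which to evaluate the curve (strictly
#'   positive, increasing). Default: `grid_size` log-spaced points spanning
#'   the fitted data's reference range.
#' @param grid_size Number of default grid points (default 100).
#' @param conf_level Confidence level for the band (default the fit's).
#' @return A tibble of class `pb_curve` with columns `conc`, `pb`,
#'   `ci_low`, `ci_high`, and attributes `slope`, `intercept`,
#'   `pb_asymptote` (`100 (b - 1)`) and `identity_crossing` (the
#'   concentration `a/(1 - b)` where the line crosses identity and PB
#'   changes sign, `NA` if none in (0, Inf)).
#' @examples
#' d <- paired_dataset(c(0.5, 1, 2, 4, 8, 1.5, 3, 6, 0.8, 5),
#'                     c(0.8, 1.3, 2.3, 4.2, 8.1, 1.8, 3.3, 6.3, 1.1, 5.3))
#' head(pb_curve(deming_fit(d)))
#' @export
pb_curve <- function(fit, grid = NULL, grid_size = 100,
                     conf_level = fit$conf_level) {
  stopifnot(inherits(fit, "deming_fit"))
  if (is.null(fit$loo)) {
    ab_abort("Proportional-bias bands need leave-one-out estimates; run `jackknife_ci()` first.",
             "assaybias_config_error")
  }
  if (is.null(grid)) {
    r <- range(fit$x)
    grid <- exp(seq(log(r[1]), log(r[2]), length.out = grid_size))
  }
  if (any(grid <= 0)) {
    ab_abort("PB is undefined at non-positive concentrations.",
             "assaybias_positivity_error")
  }
  grid <- sort(grid)
  pb_at <- function(slope, intercept, conc) {
    100 * (slope - 1 + intercept / conc)
  }
  pb <- pb_at(fit$slope, fit$intercept, grid)
  # jack-knife SE of PB at each grid point from the leave-one-out lines
  loo_pb <- outer(seq_len(nrow(fit$loo)), grid, function(i, conc) {
    pb_at(fit$loo$slope[i], fit$loo$intercept[i], conc)
  })
  se <- apply(loo_pb, 2, .jackknife_se)
  tq <- qt(1 - (1 - conf_level) / 2, df = fit$n - 2)
  crossing <- if (fit$slope != 1) fit$intercept / (1 - fit$slope) else NA_real_
  if (!is.na(crossing) && crossing <= 0) crossing <- NA_real_
  out <- tibble::tibble(
    conc = grid, pb = pb,
    ci_low = pb - tq * se, ci_high = pb + tq * se
  )
  structure(out,
            class = c("pb_curve", class(out)),
            slope = fit$slope, intercept = fit$intercept,
            pb_asymptote = 100 * (fit$slope - 1),
            identity_crossing = crossing,
            conf_level = conf_level)
}
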