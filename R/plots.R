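#' Bland-Altman plot of paired differences
#'
#' Differences (test minus reference) against the chosen abscissa, with
#' the mean difference and the 95% limits of agreement as horizontal
#' guides.
#'
#' @param bias A [bias_summary()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(bias) {
  stopifnot(inherits(bias, "bias_summary"))
  xlab <- if (bias$ba_axis == "reference") {
    "Reference concentration"
  } else {
    "Mean of methods"
  }
  ggplot2::ggplot(bias$samples, ggplot2::aes(x = .data$ba_x, y = .data$ab)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = bias$ba_mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(bias$ba_loa_low, bias$ba_loa_high),
                        colour = "steelblue", linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = xlab, y = "Absolute bias (test - reference)",
      title = if (!is.na(bias$analyte)) bias$analyte else NULL,
      subtitle = sprintf("mean AB %.3g, LoA [%.3g, %.3g]",
                         bias$ba_mean_diff, bias$ba_loa_low, bias$ba_loa_high)
    )
}

#' @export
autoplot.bias_summary <- function(object, ...) plot_bland_altman(object)

#' Proportional-bias curve with confidence band
#'
#' @param pb A [pb_curve()].
#' @return A ggplot object.
#' @export
plot_pb_curve <- function(pb) {
  stopifnot(inherits(pb, "pb_curve"))
  ggplot2::ggplot(pb, ggplot2::aes(x = .data$conc, y = .data$pb)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration", y = "Proportional bias (%)")
}

#' @export
autoplot.pb_curve <- function(object, ...) plot_pb_curve(object)

#' Regression plot: data, fitted line and identity
#'
#' Scatter of test against reference with the fitted Deming line, a
#' jack-knifed pointwise confidence band (when available), and the dotted
#' identity line the comparability criteria refer to.
#'
#' @param fit A [deming_fit()].
#' @return A ggplot object.
#' @export
plot_regression <- function(fit) {
  stopifnot(inherits(fit, "deming_fit"))
  d <- tibble::tibble(reference = fit$x, test = fit$y)
  grid <- seq(min(fit$x), max(fit$x), length.out = 100)
  band <- NULL
  if (!is.null(fit$loo)) {
    preds <- outer(seq_len(nrow(fit$loo)), grid, function(i, g) {
      fit$loo$intercept[i] + fit$loo$slope[i] * g
    })
    se <- apply(preds, 2, .jackknife_se)
    tq <- qt(1 - (1 - fit$conf_level) / 2, df = fit$n - 2)
    yhat <- fit$intercept + fit$slope * grid
    band <- tibble::tibble(reference = grid, fit = yhat,
                           lo = yhat - tq * se, hi = yhat + tq * se)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$reference, y = .data$test))
  if (!is.null(band)) {
    p <- p + ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$reference, ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE, fill = "grey80"
    )
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Reference method", y = "Test method",
      subtitle = sprintf("slope %.3f [%.3f, %.3f], intercept %.3g [%.3g, %.3g]",
                         fit$slope, fit$slope_ci[1], fit$slope_ci[2],
                         fit$intercept, fit$intercept_ci[1],
                         fit$intercept_ci[2])
    )
}

#' @export
autoplot.deming_fit <- function(object, ...) plot_regression(object)

#' Slope/intercept confidence-interval overview for a report
#'
#' One panel per parameter, one row per analyte, interval whiskers with
#' the comparability reference value (1 for the slope, 0 for the
#' intercept) as a dotted guide.
#'
#' @param report A [run_comparison()] result.
#' @return A ggplot object.
#' @export
plot_ci_overview <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  long <- dplyr::bind_rows(
    tibble::tibble(analyte = report$analyte, parameter = "slope",
                   estimate = report$slope, lo = report$slope_ci_low,
                   hi = report$slope_ci_high, ref = 1),
    tibble::tibble(analyte = report$analyte, parameter = "intercept",
                   estimate = report$intercept, lo = report$intercept_ci_low,
                   hi = report$intercept_ci_high, ref = 0)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate, y = .data$analyte)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$ref),
                        linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "Estimate (95% jack-knife CI)", y = NULL)
}

#' @export
autoplot.comparison_report <- function(object, ...) plot_ci_overview(object)
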