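# ---- internal closed-form machinery -----------------------------------------
#
# Convention used throughout: lambda = var(measurement error in y) /
# var(measurement error in x). The closed-form slope solves the
# errors-in-variables objective sum[(y - a - b*xi)^2 + lambda*(x - xi)^2]
# profiled over the latent true values xi. lambda -> Inf recovers ordinary
# least squares of y on x (x treated as error-free); lambda = 1 is orthogonal
# (total least squares) regression.

.deming_wls <- function(x, y, w, lambda) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  dx <- x - mx
  dy <- y - my
  sxx <- sum(w * dx * dx)
  syy <- sum(w * dy * dy)
  sxy <- sum(w * dx * dy)
  if (sxx <= 0 || abs(sxy) < .Machine$double.eps * max(sxx, syy, 1)) {
    ab_abort(
      "Degenerate input: zero x-spread or zero x-y covariance; the Deming slope is undefined.",
      "assaybias_singular_fit"
    )
  }
  d <- syy - lambda * sxx
  slope <- (d + sqrt(d * d + 4 * lambda * sxy * sxy)) / (2 * sxy)
  list(slope = slope, intercept = my - slope * mx)
}

# latent true-value estimates given a fitted line (minimizer of the
# objective over xi for fixed slope/intercept)
.deming_xhat <- function(x, y, slope, intercept, lambda) {
  (lambda * x + slope * (y - intercept)) / (lambda + slope * slope)
}

# one full fit on bare vectors; returns a plain list (hot path: called
# n + 1 times per jack-knife, thousands of times in simulations)
.deming_core <- function(x, y, lambda, weighted, max_iter, tol,
                         w_start = NULL) {
  n <- length(x)
  if (n < 3) {
    ab_abort("At least 3 paired samples are required for a Deming fit.",
             "assaybias_insufficient_data")
  }
  if (!weighted) {
    fit <- .deming_wls(x, y, rep(1, n), lambda)
    xhat <- .deming_xhat(x, y, fit$slope, fit$intercept, lambda)
    return(list(slope = fit$slope, intercept = fit$intercept,
                weights = rep(1, n), xhat = xhat, n_iter = 1L,
                converged = TRUE))
  }
  w <- if (is.null(w_start)) {
    d0 <- (x + y) / 2
    1 / (d0 * d0)
  } else {
    w_start
  }
  fit <- .deming_wls(x, y, w, lambda)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    xhat <- .deming_xhat(x, y, fit$slope, fit$intercept, lambda)
    if (any(xhat <= 0)) {
      bad <- which(xhat <= 0)
      ab_abort(
        paste0("Weight degeneracy: estimated true concentration is ",
               "non-positive for sample(s) ",
               paste(head(bad, 5), collapse = ", "),
               "; constant-CV weights 1/xhat^2 are undefined."),
        "assaybias_weight_degeneracy", samples = bad
      )
    }
    w <- 1 / (xhat * xhat)
    new <- .deming_wls(x, y, w, lambda)
    # damp after the initial fast phase: the plain fixed-point update can
    # fall into a two-cycle on noisy low-concentration-heavy data; averaging
    # kills the cycle without moving the fixed point
    if (it > 10L) {
      new$slope <- (new$slope + fit$slope) / 2
      new$intercept <- (new$intercept + fit$intercept) / 2
    }
    scale <- 1 / mean(xhat)
    delta <- abs(new$slope - fit$slope) +
      abs(new$intercept - fit$intercept) * scale
    fit <- new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    ab_abort(
      paste0("Weighted Deming fit did not converge in ", max_iter,
             " iterations (tol = ", format(tol), ")."),
      "assaybias_nonconvergence"
    )
  }
  xhat <- .deming_xhat(x, y, fit$slope, fit$intercept, lambda)
  list(slope = fit$slope, intercept = fit$intercept, weights = w,
       xhat = xhat, n_iter = it, converged = TRUE)
}

# jack-knife SEs from leave-one-out estimates:
# SE = sqrt(((n-1)/n) * sum((theta_i - mean(theta_i))^2))
.jackknife_se <- function(theta_loo) {
  n <- length(theta_loo)
  m <- mean(theta_loo)
  sqrt((n - 1) / n * sum((theta_loo - m)^2))
}

# ---- user-facing fit ---------------------------------------------------------

#' Fit a (weighted) Deming regression to paired measurements
#'
#' Errors-in-variables regression of the test method on the reference
#' method, assuming measurement error in both. The weighted variant
#' (default) uses constant-CV weights `1/xhat^2`, where `xhat` is the
#' estimated true concentration, re-estimated until convergence — the
#' appropriate model when assay imprecision scales with concentration
#' (heteroscedasticity), as is typical for immunoassays. Jack-knife
#' (leave-one-out) standard errors and t-based confidence intervals for the
#' slope and intercept are computed by default.
#'
#' @param data A data frame of paired measurements (see [paired_dataset()]).
#' @param reference,test Columns of `data` holding the reference- and
#'   test-method concentrations (unquoted); default to columns named
#'   `reference` and `test`.
#' @param weighted If `TRUE` (default), iteratively reweighted constant-CV
#'   fit; if `FALSE`, a single unweighted (simple Deming) fit.
#' @param lambda Ratio of the test-method to reference-method measurement
#'   error *variances*, `var(err_y)/var(err_x)`. Default 1 (equal error,
#'   orthogonal regression), the usual choice when no replicate data are
#'   available to estimate it.
#' @param jackknife If `TRUE` (default), compute leave-one-out standard
#'   errors and confidence intervals.
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @param min_n_jackknife Minimum number of samples required before
#'   jack-knife intervals are computed (default 10); below this the
#'   jack-knife is refused rather than returning unstable intervals.
#' @param max_iter,tol Convergence controls for the reweighting loop: stop
#'   when `|d_slope| + |d_intercept|/mean(xhat) < tol` (defaults 100, 1e-8).
#'   Non-convergence is an error, never a silent result.
#'
#' @return An object of class `deming_fit`: a list with components `slope`,
#'   `intercept`, `slope_se`, `intercept_se`, `slope_ci`, `intercept_ci`
#'   (length-2 vectors), `residuals` (`y - (a + b x)`), `std_residuals`
#'   (weighted residuals centred and scaled to unit variance), `weights`,
#'   `xhat` (estimated true concentrations), `loo` (tibble of leave-one-out
#'   slope/intercept estimates, reused by [pb_curve()]), `n`, `n_iter`,
#'   `converged`, `lambda`, `weighted`, `conf_level` and the input vectors
#'   `x`, `y`. Supports [tidy()], [glance()], [augment()] and [autoplot()].
#'
#' @details
#' The slope is the closed-form root
#' \deqn{b = \frac{S_{yy} - \lambda S_{xx} +
#'   \sqrt{(S_{yy} - \lambda S_{xx})^2 + 4\lambda S_{xy}^2}}{2 S_{xy}},}
#' with (weighted) centred sums of squares and cross-products, and the
#' intercept is \eqn{\bar y - b \bar x}. As `lambda` grows (reference
#' error negligible) the slope approaches the ordinary least-squares slope.
#' Latent concentrations are
#' \eqn{\hat\xi_i = (\lambda x_i + b (y_i - a)) / (\lambda + b^2)}.
#' Initial weights use the proxy `(x + y)/2` for the true concentration.
#'
#' Jack-knife standard errors follow
#' \eqn{SE(\theta) = \sqrt{\frac{n-1}{n}\sum_i (\theta_{(i)} -
#' \bar\theta_{(\cdot)})^2}} and intervals are
#' \eqn{\hat\theta \pm t_{1-\alpha/2,\,n-2}\,SE(\theta)}.
#'
#' @examples
#' d <- paired_dataset(c(0.5, 1, 2, 4, 8, 1.5, 3, 6, 0.8, 5),
#'                     c(0.55, 1.1, 2.1, 4.4, 8.2, 1.6, 3.2, 6.5, 0.9, 5.4))
#' fit <- deming_fit(d)
#' tidy(fit)
#' @export
deming_fit <- function(data, reference = NULL, test = NULL,
                       weighted = TRUE, lambda = 1,
                       jackknife = TRUE, conf_level = 0.95,
                       min_n_jackknife = 10,
                       max_iter = 100, tol = 1e-8) {
  xy <- extract_xy(data, {{ reference }}, {{ test }})
  x <- xy$x
  y <- xy$y
  validate_paired_data(tibble::tibble(reference = x, test = y))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    ab_abort("`lambda` must be a single positive number.",
             "assaybias_config_error")
  }
  n <- length(x)
  core <- .deming_core(x, y, lambda, weighted, max_iter, tol)

  res <- y - (core$intercept + core$slope * x)
  wres <- sqrt(core$weights) * res
  std_res <- as.numeric(scale(wres))  # centred, unit sample SD

  fit <- structure(
    list(
      slope = core$slope, intercept = core$intercept,
      slope_se = NA_real_, intercept_se = NA_real_,
      slope_ci = c(NA_real_, NA_real_), intercept_ci = c(NA_real_, NA_real_),
      residuals = res, std_residuals = std_res,
      weights = core$weights, xhat = core$xhat,
      loo = NULL, n = n, n_iter = core$n_iter, converged = core$converged,
      lambda = lambda, weighted = weighted, conf_level = conf_level,
      max_iter = max_iter, tol = tol, x = x, y = y,
      analyte = if ("analyte" %in% names(data)) data$analyte[1] else NA_character_,
      unit = if ("unit" %in% names(data)) data$unit[1] else NA_character_
    ),
    class = "deming_fit"
  )
  if (jackknife) fit <- jackknife_ci(fit, conf_level = conf_level,
                                     min_n = min_n_jackknife)
  fit
}

#' Jack-knife standard errors and confidence intervals for a Deming fit
#'
#' Refits the regression on each leave-one-out subset, computes jack-knife
#' standard errors for the slope and intercept, and attaches t-based
#' confidence intervals (degrees of freedom `n - 2`). The leave-one-out
#' estimates are stored on the returned fit and reused by [pb_curve()] for
#' pointwise confidence bands.
#'
#' @param fit A [deming_fit()] object.
#' @param conf_level Confidence level (default the fit's own, 0.95).
#' @param min_n Minimum sample size (default 10); the jack-knife is refused
#'   below this rather than returning unstable intervals.
#' @return The fit with `slope_se`, `intercept_se`, `slope_ci`,
#'   `intercept_ci` and `loo` populated.
#' @export
jackknife_ci <- function(fit, conf_level = fit$conf_level, min_n = 10) {
  stopifnot(inherits(fit, "deming_fit"))
  n <- fit$n
  if (n < min_n) {
    ab_abort(
      paste0("Jack-knife intervals require at least ", min_n,
             " samples (got ", n, "); refusing to report unstable intervals."),
      "assaybias_insufficient_data"
    )
  }
  x <- fit$x
  y <- fit$y
  slopes <- numeric(n)
  intercepts <- numeric(n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    li <- tryCatch(
      .deming_core(x[-i], y[-i], fit$lambda, fit$weighted, fit$max_iter,
                   fit$tol),
      error = function(e) NULL
    )
    if (is.null(li)) {
      failed <- c(failed, i)
    } else {
      slopes[i] <- li$slope
      intercepts[i] <- li$intercept
    }
  }
  if (length(failed) > 0) {
    ab_abort(
      paste0("Leave-one-out refit failed for sample(s) ",
             paste(head(failed, 10), collapse = ", "), "."),
      "assaybias_jackknife_error", samples = failed
    )
  }
  alpha <- 1 - conf_level
  tq <- qt(1 - alpha / 2, df = n - 2)
  fit$slope_se <- .jackknife_se(slopes)
  fit$intercept_se <- .jackknife_se(intercepts)
  fit$slope_ci <- fit$slope + c(-1, 1) * tq * fit$slope_se
  fit$intercept_ci <- fit$intercept + c(-1, 1) * tq * fit$intercept_se
  fit$conf_level <- conf_level
  fit$loo <- tibble::tibble(slope = slopes, intercept = intercepts)
  fit
}

# ---- methods -----------------------------------------------------------------

#' @export
print.deming_fit <- function(x, ...) {
  kind <- if (x$weighted) "Weighted Deming" else "Simple Deming"
  cat(kind, " regression (lambda = ", format(x$lambda), ", n = ", x$n,
      ")\n", sep = "")
  cat(sprintf("  slope:     %.4f", x$slope))
  if (!is.na(x$slope_se)) {
    cat(sprintf("  [%.4f, %.4f] (%d%% jack-knife CI)",
                x$slope_ci[1], x$slope_ci[2], round(100 * x$conf_level)))
  }
  cat("\n")
  cat(sprintf("  intercept: %.4f", x$intercept))
  if (!is.na(x$intercept_se)) {
    cat(sprintf("  [%.4f, %.4f]", x$intercept_ci[1], x$intercept_ci[2]))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a Deming fit into a one-row-per-term tibble
#'
#' @param x A `deming_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.deming_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    std.error = c(x$slope_se, x$intercept_se),
    conf.low = c(x$slope_ci[1], x$intercept_ci[1]),
    conf.high = c(x$slope_ci[2], x$intercept_ci[2])
  )
}

#' @export
glance.deming_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, lambda = x$lambda, weighted = x$weighted,
    n_iter = x$n_iter, converged = x$converged,
    conf.level = x$conf_level
  )
}

#' @export
augment.deming_fit <- function(x, ...) {
  tibble::tibble(
    reference = x$x, test = x$y,
    .fitted = x$intercept + x$slope * x$x,
    .resid = x$residuals,
    .std.resid = x$std_residuals,
    .weight = x$weights,
    .xhat = x$xhat
  )
}
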