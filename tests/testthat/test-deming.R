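test_that("exact data give exact Deming estimates", {
  f <- deming_fit(paired_dataset(c(1, 2, 3), c(1, 2, 3)), jackknife = FALSE)
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)

  f2 <- deming_fit(paired_dataset(c(1, 2, 3), c(2, 4, 6)), jackknife = FALSE)
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 0, tolerance = 1e-12)

  # weighted identity converges immediately
  fw <- deming_fit(paired_dataset(c(0.5, 1, 2, 4, 8), c(0.5, 1, 2, 4, 8)),
                   weighted = TRUE, jackknife = FALSE)
  expect_equal(fw$slope, 1, tolerance = 1e-10)
  expect_equal(fw$intercept, 0, tolerance = 1e-10)
  expect_equal(fw$n_iter, 1L)
  expect_true(fw$converged)
})

test_that("closed-form fit matches brute-force minimization of the Deming objective", {
  d <- fixture_noisy(8)
  for (lambda in c(0.5, 1, 2)) {
    f <- deming_fit(d, weighted = FALSE, lambda = lambda, jackknife = FALSE)
    bf <- deming_brute_force(d$reference, d$test, lambda)
    expect_equal(f$slope, bf$slope, tolerance = 1e-6)
    expect_equal(f$intercept, bf$intercept, tolerance = 1e-6)
  }
})

test_that("lambda = 1 simple Deming equals closed-form orthogonal regression", {
  d <- fixture_noisy(10, seed = 202)
  f <- deming_fit(d, weighted = FALSE, lambda = 1, jackknife = FALSE)
  o <- tls_fit(d$reference, d$test)
  expect_equal(f$slope, o$slope, tolerance = 1e-10)
  expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
})

test_that("slope approaches the OLS slope monotonically as x-error vanishes", {
  d <- fixture_noisy(12, seed = 303)
  ols <- unname(coef(lm(test ~ reference, data = d))[2])
  lambdas <- c(1, 10, 100, 1e4, 1e6)
  slopes <- vapply(lambdas, function(l) {
    deming_fit(d, weighted = FALSE, lambda = l, jackknife = FALSE)$slope
  }, numeric(1))
  gaps <- abs(slopes - ols)
  expect_true(all(diff(gaps) < 0))
  expect_equal(slopes[length(slopes)], ols, tolerance = 1e-4)
})

test_that("rescaling both axes leaves the slope unchanged and scales the intercept", {
  d <- fixture_noisy(15, seed = 404)
  for (weighted in c(FALSE, TRUE)) {
    f1 <- deming_fit(d, weighted = weighted, jackknife = FALSE)
    c_scale <- 3.7
    d2 <- paired_dataset(d$reference * c_scale, d$test * c_scale)
    f2 <- deming_fit(d2, weighted = weighted, jackknife = FALSE)
    expect_equal(f2$slope, f1$slope, tolerance = 1e-9)
    expect_equal(f2$intercept, f1$intercept * c_scale, tolerance = 1e-9)
  }
})

test_that("weighted fit is invariant to sample order", {
  d <- fixture_proportional(40, seed = 11)
  f1 <- deming_fit(d, jackknife = FALSE)
  perm <- withr::with_seed(5, sample(nrow(d)))
  f2 <- deming_fit(d[perm, ], jackknife = FALSE)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-9)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-9)
})

test_that("weighted and simple fits agree on homoscedastic data within jack-knife error", {
  d <- withr::with_seed(21, {
    x <- runif(60, 5, 10)  # narrow range: constant absolute noise
    y <- 1.2 * x + rnorm(60, 0, 0.2)
    paired_dataset(x, abs(y))
  })
  fw <- deming_fit(d, weighted = TRUE)
  fs <- deming_fit(d, weighted = FALSE, jackknife = FALSE)
  expect_lt(abs(fw$slope - fs$slope), 2 * fw$slope_se)
})

test_that("weighted fit recovers a proportional calibration slope", {
  d <- fixture_proportional(200, slope = 1.3, cv = 0.05, seed = 31)
  f <- deming_fit(d, jackknife = FALSE)
  expect_gt(f$slope, 1.25)
  expect_lt(f$slope, 1.35)
})

test_that("standardized residuals are centred and unit-scaled", {
  d <- fixture_proportional(49, seed = 41)
  f <- deming_fit(d, jackknife = FALSE)
  expect_lt(abs(mean(f$std_residuals)), 1e-8)
  expect_equal(sd(f$std_residuals), 1, tolerance = 1e-10)
  expect_length(f$residuals, 49)
})

test_that("degenerate and undersized inputs raise classed errors", {
  expect_error(deming_fit(paired_dataset(c(1, 2), c(1, 2))),
               class = "assaybias_insufficient_data")
  # all x equal: zero x-spread
  expect_error(
    deming_fit(tibble::tibble(reference = c(2, 2, 2, 2),
                              test = c(1, 2, 3, 4)), jackknife = FALSE),
    class = "assaybias_singular_fit"
  )
  expect_error(deming_fit(fixture_noisy(8), lambda = -1),
               class = "assaybias_config_error")
  expect_error(
    deming_fit(tibble::tibble(reference = c(1, 2, 0, 4),
                              test = c(1, 2, 3, 4))),
    class = "assaybias_positivity_error"
  )
})

test_that("non-convergence is an error, not a silent result", {
  d <- fixture_proportional(30, seed = 51)
  expect_error(deming_fit(d, max_iter = 1, tol = 1e-16, jackknife = FALSE),
               class = "assaybias_nonconvergence")
})

test_that("tidy/glance/augment return the documented tibbles", {
  d <- fixture_proportional(20, seed = 61)
  f <- deming_fit(d)
  td <- tidy(f)
  expect_equal(td$term, c("slope", "intercept"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(f)
  expect_equal(gl$n, 20)
  expect_true(gl$converged)
  au <- augment(f)
  expect_equal(nrow(au), 20)
  expect_equal(au$.resid, f$residuals)
  expect_true(all(au$.weight > 0 & is.finite(au$.weight)))
})
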