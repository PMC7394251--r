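test_that("Pearson correlation matches the textbook formula and handles exact lines", {
  expect_equal(pearson_correlation(paired_dataset(1:5, 2 * (1:5) + 1)), 1)
  d_neg <- tibble::tibble(reference = 1:5, test = -(1:5))
  expect_equal(pearson_correlation(d_neg), -1)
  d <- fixture_noisy(10, seed = 321)
  x <- d$reference; y <- d$test
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(d), r_direct, tolerance = 1e-12)
  expect_error(
    pearson_correlation(tibble::tibble(reference = c(1, 1, 1), test = 1:3)),
    class = "assaybias_singular_fit"
  )
})

test_that("Anderson-Darling statistic matches an independent direct computation", {
  # fixture with externally verified A2 (cross-checked against an
  # independent implementation): A2 = 0.9467718796
  v <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195, 236)
  res <- ad_normality(v)
  expect_equal(res$statistic, 0.9467718796, tolerance = 1e-3)
  # direct formula: A2 from the normal CDF of standardized order statistics,
  # D'Agostino small-sample correction applied inside the p approximation
  n <- length(v)
  z <- sort((v - mean(v)) / sd(v))
  p <- pnorm(z)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(p) + log(1 - rev(p))))
  expect_equal(res$statistic, a2, tolerance = 1e-10)
  expect_lt(res$p.value, 0.05)  # clearly non-normal vector
  expect_error(ad_normality(rnorm(5)), class = "assaybias_insufficient_data")
})

test_that("Anderson-Darling holds its size under the null and rejects skew", {
  null_p <- vapply(1:100, function(r) {
    ad_normality(withr::with_seed(4000 + r, rnorm(500)))$p.value
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.90)
  skew_p <- vapply(1:100, function(r) {
    ad_normality(withr::with_seed(6000 + r, exp(rnorm(200))))$p.value
  }, numeric(1))
  expect_gte(mean(skew_p < 0.05), 0.95)
})

test_that("alternating residual signs give a small CUSUM statistic and large p", {
  x <- seq(1, 5, length.out = 20)
  y <- x + rep(c(0.01, -0.01), 10)
  f <- deming_fit(paired_dataset(x, y), jackknife = FALSE)
  res <- cusum_linearity(f, method = "asymptotic")
  expect_lt(res$statistic, 0.6)
  expect_gt(res$p.value, 0.8)
  resb <- cusum_linearity(f)
  expect_gt(resb$p.value, 0.5)
})

test_that("a strong quadratic relationship is flagged as nonlinear", {
  rej <- vapply(1:20, function(r) {
    d <- withr::with_seed(7000 + r, {
      x <- runif(50, 0.5, 5)
      paired_dataset(x, x^2 * (1 + rnorm(50, 0, 0.05)))
    })
    f <- deming_fit(d, jackknife = FALSE)
    cusum_linearity(f)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("one-signed residuals yield the maximal statistic with a warning", {
  f <- deming_fit(fixture_noisy(12, seed = 111), jackknife = FALSE)
  f$residuals <- abs(f$residuals) + 0.01
  expect_warning(res <- cusum_linearity(f), "one sign")
  expect_equal(res$statistic, sqrt(f$n))
  expect_equal(res$p.value, 0)
})

test_that("CUSUM p-values are deterministic across calls", {
  f <- deming_fit(fixture_proportional(49, seed = 13), jackknife = FALSE)
  expect_identical(cusum_linearity(f), cusum_linearity(f))
})

test_that("diagnostics bundle is invariant to joint unit rescaling", {
  d <- fixture_proportional(30, seed = 17)
  f1 <- deming_fit(d)
  d2 <- paired_dataset(d$reference * 1000, d$test * 1000)  # nmol -> pmol
  f2 <- deming_fit(d2)
  g1 <- regression_diagnostics(f1)
  g2 <- regression_diagnostics(f2)
  expect_equal(g1$pearson_r, g2$pearson_r, tolerance = 1e-9)
  expect_equal(g1$normality_stat, g2$normality_stat, tolerance = 1e-7)
  expect_equal(g1$linearity_stat, g2$linearity_stat, tolerance = 1e-9)
  expect_equal(g1$linearity_p, g2$linearity_p, tolerance = 1e-9)
})

test_that("diagnostics report all documented columns with valid ranges", {
  f <- deming_fit(fixture_proportional(49, seed = 19))
  g <- regression_diagnostics(f)
  expect_true(g$pearson_r >= -1 && g$pearson_r <= 1)
  expect_true(g$normality_p >= 0 && g$normality_p <= 1)
  expect_true(g$linearity_p >= 0 && g$linearity_p <= 1)
  expect_identical(g$normality_ok, g$normality_p >= g$alpha)
  expect_identical(g$linearity_ok, g$linearity_p >= g$alpha)
})
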