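test_that("generation is bit-reproducible under a seed and varies across seeds", {
  sc <- dplyr::slice(preset_scenarios(), 3)
  d1 <- generate_paired_dataset(sc)
  d2 <- generate_paired_dataset(sc)
  expect_identical(d1, d2)
  d3 <- generate_paired_dataset(sc, seed = sc$seed + 1)
  expect_false(identical(d1$reference, d3$reference))
  expect_identical(sample_true_concentrations(sc),
                   sample_true_concentrations(sc))
})

test_that("true concentrations respect the truncation bounds and degenerate range", {
  sc <- synthetic_scenario(n = 500, log_mean = 0, log_sd = 1,
                           conc_range = c(0.5, 3))
  tr <- sample_true_concentrations(sc, seed = 2)
  expect_true(all(tr >= 0.5 & tr <= 3))
  scd <- synthetic_scenario(n = 20, conc_range = c(1, 1))
  expect_equal(sample_true_concentrations(scd), rep(1, 20))
  sc_bad <- synthetic_scenario(n = 20, log_mean = 0, log_sd = 0.1,
                               conc_range = c(1e6, 2e6))
  expect_error(sample_true_concentrations(sc_bad),
               class = "assaybias_config_error")
})

test_that("testosterone and progesterone presets emphasise low concentrations", {
  pr <- preset_scenarios()
  sc_t <- pr[pr$analyte == "testosterone", ]
  class(sc_t) <- class(pr)
  frac_t <- vapply(1:50, function(r) {
    mean(sample_true_concentrations(sc_t, seed = 500 + r) < 2.0)
  }, numeric(1))
  expect_gte(min(frac_t), 0.6)
  sc_p <- pr[pr$analyte == "progesterone", ]
  class(sc_p) <- class(pr)
  frac_p <- vapply(1:50, function(r) {
    mean(sample_true_concentrations(sc_p, seed = 700 + r) < 1.0)
  }, numeric(1))
  expect_gte(min(frac_p), 0.6)
})

test_that("noise-free generation reproduces the calibration line exactly", {
  # CVs cannot be zero by construction; drive them to the permitted floor
  sc <- synthetic_scenario(n = 30, log_mean = 0, log_sd = 0.5,
                           conc_range = c(0.5, 4),
                           ref_cv = 1e-9, test_cv = 1e-9,
                           calib_slope = 1, calib_intercept = 0)
  d <- generate_paired_dataset(sc, seed = 5)
  expect_equal(d$reference, d$test, tolerance = 1e-7)
  expect_equal(d$reference, d$true_conc, tolerance = 1e-7)
  sc13 <- synthetic_scenario(n = 30, log_mean = 0, log_sd = 0.5,
                             conc_range = c(0.5, 4),
                             ref_cv = 1e-9, test_cv = 1e-9,
                             calib_slope = 1.3)
  d13 <- generate_paired_dataset(sc13, seed = 5)
  b <- bias_summary(d13)
  expect_equal(b$mean_rb, 30, tolerance = 1e-5)
})

test_that("interferent-only bias vanishes at high concentration through the pipeline", {
  sc <- synthetic_scenario(n = 150, log_mean = log(3), log_sd = 0.8,
                           conc_range = c(0.3, 60),
                           ref_cv = 0.05, test_cv = 0.05,
                           calib_slope = 1, interferent_level = 0.15)
  d <- generate_paired_dataset(sc, seed = 9)
  f <- deming_fit(d)
  pb <- pb_curve(f)
  expect_true(all(diff(pb$pb) < 0))        # decreasing along the axis
  # large-C limit 100 (slope - 1): within the jack-knife CI of 0
  tq <- qt(0.975, f$n - 2)
  asym <- 100 * (f$slope - 1)
  expect_lt(abs(asym), tq * 100 * f$slope_se)
})

test_that("preset structure matches its documented roles", {
  pr <- preset_scenarios()
  expect_equal(nrow(pr), 6)
  expect_setequal(pr$analyte, c("aldosterone", "cortisol", "DHEAS",
                                "testosterone", "progesterone", "OHP"))
  cortisol <- pr[pr$analyte == "cortisol", ]
  expect_lt(cortisol$calib_slope, 1)
  expect_equal(cortisol$interferent_level, 0)
  others <- pr[pr$analyte != "cortisol", ]
  expect_true(all(others$calib_slope > 1 | others$interferent_level > 0))
  expect_true(all(pr$conc_low > 0))
  expect_true(all(pr$ref_cv > 0 & pr$ref_cv < 0.5))
})

test_that("invalid scenario configurations are rejected", {
  expect_error(synthetic_scenario(conc_range = c(-1, 5)),
               class = "assaybias_config_error")
  expect_error(synthetic_scenario(ref_cv = 0.7),
               class = "assaybias_config_error")
  expect_error(synthetic_scenario(n = 5), class = "assaybias_config_error")
  expect_error(
    generate_paired_dataset(preset_scenarios()),  # six rows at once
    class = "assaybias_config_error"
  )
})
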