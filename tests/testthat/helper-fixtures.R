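# fixtures shared across test files; all generated in code, fixed seeds

# small noisy paired instance around slope 1.1, intercept 0.2
fixture_noisy <- function(n = 8, seed = 101) {
  withr::with_seed(seed, {
    x <- exp(rnorm(n, log(3), 0.7))
    y <- (0.2 + 1.1 * x) * (1 + rnorm(n, 0, 0.06))
    paired_dataset(abs(x), abs(y))
  })
}

# proportional-noise dataset with known calibration
fixture_proportional <- function(n, slope = 1.3, cv = 0.05, seed = 7,
                                 log_mean = log(2), log_sd = 0.9) {
  sc <- synthetic_scenario(
    n = n, log_mean = log_mean, log_sd = log_sd,
    conc_range = c(0.05, 100), ref_cv = cv, test_cv = cv / slope,
    calib_slope = slope
  )
  generate_paired_dataset(sc, seed = seed)
}

# brute-force minimizer of the Deming objective
#   sum_i (y_i - b0 - b1 xi_i)^2 + lambda (x_i - xi_i)^2
# over (b0, b1, xi_1..xi_n); independent oracle for the closed form
deming_brute_force <- function(x, y, lambda) {
  n <- length(x)
  obj <- function(par) {
    b0 <- par[1]; b1 <- par[2]; xi <- par[-(1:2)]
    sum((y - b0 - b1 * xi)^2 + lambda * (x - xi)^2)
  }
  ols <- stats::lm(y ~ x)
  start <- unname(c(coef(ols), x))
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  list(intercept = opt$par[1], slope = opt$par[2], value = opt$value)
}

# orthogonal (total least squares) slope via eigen decomposition of the
# covariance matrix; independent closed-form oracle for lambda = 1
tls_fit <- function(x, y) {
  ev <- eigen(stats::cov(cbind(x, y)))
  v <- ev$vectors[, 2]  # eigenvector of the smallest eigenvalue (normal dir)
  slope <- -v[1] / v[2]
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}
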