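test_that("fit_linear matches the closed-form least-squares solution", {
  x <- canonical_grid("OS")
  set.seed(3)
  y <- -0.006143 * x + 1.274 + rnorm(length(x), 0, 0.05)
  f <- fit_linear(x, y)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(f$P1, slope, tolerance = 1e-10)
  expect_equal(f$P2, intercept, tolerance = 1e-10)
  # exact linear data recovered exactly
  f0 <- fit_linear(x, -0.006143 * x + 1.274)
  expect_equal(f0$P1, -0.006143, tolerance = 1e-12)
  expect_equal(f0$P2, 1.274, tolerance = 1e-12)
  expect_equal(f0$r_squared, 1)
})

test_that("symmetric perturbations leave the fitted slope unchanged", {
  x <- 1:9
  y <- 2 * x + 1
  eps <- 0.25
  y_pert <- y
  # equal bumps at points mirrored about the centre shift the intercept
  # but cancel in the slope estimate
  y_pert[2] <- y_pert[2] + eps
  y_pert[8] <- y_pert[8] + eps
  expect_equal(fit_linear(x, y_pert)$P1, fit_linear(x, y)$P1,
               tolerance = 1e-12)
  expect_gt(fit_linear(x, y_pert)$P2, fit_linear(x, y)$P2)
})

test_that("fit_power recovers every reference power law from noiseless data", {
  for (row in table2_laws()) {
    if (row$model != "power") next
    p <- row$parameter
    x <- canonical_grid(p)
    y <- row$A * x^row$B + row$C
    f <- fit_power(x, y)
    expect_equal(f$A, row$A, tolerance = 1e-4)
    expect_equal(f$B, row$B, tolerance = 1e-4)
    expect_equal(f$C, row$C, tolerance = 1e-4)
    expect_equal(f$r_squared, 1, tolerance = 1e-8)
  }
})

test_that("fitting data generated from a fit reproduces that fit", {
  x <- canonical_grid("t")
  set.seed(11)
  f1 <- fit_power(x, 3.754 * x^(-1.632) - 0.08946 +
                    rnorm(length(x), 0, 0.02))
  f2 <- fit_power(x, evaluate_fit(f1, x))
  expect_equal(f2$A, f1$A, tolerance = 1e-6)
  expect_equal(f2$B, f1$B, tolerance = 1e-6)
  expect_equal(f2$C, f1$C, tolerance = 1e-6)
})

test_that("noisy coefficient recovery succeeds on the wide-range law", {
  # E law spans 1.5 decades: the three coefficients are identifiable at
  # sigma = 0.01 with a dense sampling of the range
  x <- seq(100, 3000, length.out = 300)
  mu <- 40.16 * x^(-0.5695) - 0.2011
  set.seed(1)
  f <- fit_power(x, mu + rnorm(length(x), 0, 0.01))
  expect_equal(f$A, 40.16, tolerance = 0.05)
  expect_equal(f$B, -0.5695, tolerance = 0.05)
  expect_equal(f$C, -0.2011, tolerance = 0.05)
})

test_that("noisy recovery of the narrow-range thickness law returns the curve", {
  # on t in [2, 4] the power coefficients are collinear, so the curve --
  # not each raw coefficient -- is the recoverable quantity
  x <- canonical_grid("t")
  mu <- 3.754 * x^(-1.632) - 0.08946
  set.seed(7)
  f <- fit_power(x, mu + rnorm(length(x), 0, 0.01))
  expect_lt(sqrt(mean((evaluate_fit(f, x) - mu)^2)), 0.02)
})

test_that("degenerate constant data are handled without crashing", {
  x <- canonical_grid("t")
  f <- fit_power(x, rep(1.5, length(x)))
  expect_true(f$degenerate)
  expect_identical(f$A, 0)
  expect_identical(f$r_squared, 0)
  expect_equal(evaluate_fit(f, x), rep(1.5, length(x)))
})

test_that("fit data validation rejects malformed input", {
  expect_error(fit_power(c(1, 2, 3), c(1, 2, 3)), "at least 4")
  expect_error(fit_power(c(-1, 2, 3, 4), c(1, 2, 3, 4)), "positive")
  expect_error(fit_power(c(1, 3, 2, 4), c(1, 2, 3, 4)), "increasing")
  expect_error(fit_linear(c(2, 2), c(1, 2)), "increasing")
})

test_that("surrogate evaluation and derivative match the closed forms", {
  laws <- reference_fits()
  fE <- laws[["2"]]$E
  expect_equal(evaluate_fit(fE, 100), 2.7149, tolerance = 1e-4)
  expect_equal(evaluate_fit(fE, 421), 1.0850, tolerance = 1e-4)
  expect_equal(fit_derivative(fE, 500),
               40.16 * (-0.5695) * 500^(-1.5695), tolerance = 1e-12)
  fOS <- laws[["2"]]$OS
  expect_equal(fit_derivative(fOS, c(10, 15, 20)), rep(-0.006143, 3))
  expect_error(evaluate_fit(fE, -5), "x > 0")
  # evaluating a data-carrying fit outside its range warns
  fit <- fit_power(canonical_grid("E"),
                   evaluate_fit(fE, canonical_grid("E")))
  expect_warning(evaluate_fit(fit, 5000), "outside")
})

test_that("delta-method confidence bands behave as expected", {
  x <- canonical_grid("E")
  mu <- 40.16 * x^(-0.5695) - 0.2011
  # noiseless fit: zero-width band
  f0 <- fit_power(x, mu)
  cb0 <- confidence_band(f0, x)
  expect_lt(max(cb0$upper - cb0$lower), 1e-6)
  expect_true(all(cb0$fit >= cb0$lower & cb0$fit <= cb0$upper))
  # nested levels and coverage of the true curve on noisy data
  set.seed(42)
  f <- fit_power(x, mu + rnorm(length(x), 0, 0.05))
  cb95 <- confidence_band(f, x, 0.95)
  cb99 <- confidence_band(f, x, 0.99)
  expect_true(all(cb99$lower <= cb95$lower & cb99$upper >= cb95$upper))
  expect_gte(mean(mu >= cb95$lower & mu <= cb95$upper), 0.90)
  # bands require a covariance
  expect_error(confidence_band(reference_fits()[["2"]]$E, x),
               "covariance")
})
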