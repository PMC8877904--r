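test_that("fit_linear equals the normal-equations OLS solution", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- stats::rnorm(n, sd = stats::runif(1, 0.5, 20))
    y <- stats::rnorm(n, mean = 2 * x, sd = stats::runif(1, 0.1, 5))
    fit <- fit_linear(x, y)
    beta <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
    expect_equal(fit$r_squared, stats::cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("noiseless linear data built from published drift constants is recovered", {
  x <- seq(0, 25, length.out = 40)
  y <- 0.1314 * x + 1420
  fit <- fit_linear(x, y)
  expect_equal(fit$slope, 0.1314, tolerance = 1e-8)
  expect_equal(fit$intercept, 1420, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-10)
})

test_that("constant responses fall back to the documented boundary", {
  fit <- fit_linear(1:10, rep(3.5, 10))
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
  expect_equal(fit$p_value, 1)
})

test_that("degenerate linear inputs are rejected", {
  expect_error(fit_linear(1:2, 1:2), "at least 3")
  expect_error(fit_linear(rep(1, 5), stats::rnorm(5)), "zero variance")
  # NA pairs are dropped before the count check
  expect_error(fit_linear(c(1, 2, NA, NA), c(1, 2, 3, 4)), "at least 3")
})

test_that("the slope confidence interval has near-nominal coverage", {
  # generator uses a published band-3 drift slope and bench-scale noise
  slope <- 1.519
  covered <- 0
  set.seed(32)
  for (i in 1:100) {
    x <- seq(0, 25, length.out = 70)
    y <- slope * x + 3116 + stats::rnorm(70, sd = 20)
    fit <- fit_linear(x, y)
    half <- stats::qt(0.975, fit$n - 2) * fit$slope_se
    covered <- covered + (abs(fit$slope - slope) <= half)
  }
  expect_gte(covered, 93)
})

test_that("noiseless exponential data built from published constants is recovered", {
  x <- seq(0, 23, length.out = 50)
  for (p in list(c(1044, -0.0826), c(2041, -0.1519))) {
    fit <- fit_exponential(x, p[1] * exp(p[2] * x))
    expect_true(fit$converged)
    expect_equal(fit$y0, p[1], tolerance = 1e-6)
    expect_equal(fit$k, p[2], tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("exponential fit on log-linearizable data equals the log-domain fit", {
  x <- seq(0, 10, by = 0.5)
  y <- 512 * exp(-0.21 * x)
  fit <- fit_exponential(x, y)
  lf <- stats::lm(log(y) ~ x)
  expect_equal(fit$k, unname(stats::coef(lf)[2]), tolerance = 1e-8)
  expect_equal(fit$y0, exp(unname(stats::coef(lf)[1])), tolerance = 1e-6)
})

test_that("a constant energy series gives k = 0, y0 = c", {
  fit <- fit_exponential(1:10, rep(42, 10))
  expect_equal(fit$k, 0, tolerance = 1e-10)
  expect_equal(fit$y0, 42, tolerance = 1e-8)
})

test_that("non-positive energies are dropped with a message", {
  expect_message(
    fit <- fit_exponential(1:6, c(10, -1, 8, 0, 6, 5)),
    "2 non-positive"
  )
  expect_equal(fit$n, 4)
  expect_error(
    suppressMessages(fit_exponential(1:4, c(-1, 0, 0, -2))),
    "at least 3"
  )
})

test_that("exponential rate is recovered under multiplicative lognormal noise", {
  set.seed(33)
  ks <- replicate(200, {
    x <- seq(0, 25, length.out = 70)
    y <- 800 * exp(-0.15 * x) * exp(stats::rnorm(70, sd = 0.5))
    fit_exponential(x, y)$k
  })
  expect_lt(abs(stats::median(ks) - (-0.15)) / 0.15, 0.15)
})

test_that("R-squared of any fit stays in [0, 1]", {
  set.seed(34)
  for (i in 1:25) {
    x <- stats::runif(20, 0, 25)
    y <- exp(stats::rnorm(20, sd = 2))       # pure noise, no trend
    fit <- fit_exponential(x, y)
    expect_gte(fit$r_squared, 0)
    expect_lte(fit$r_squared, 1)
    lin <- fit_linear(x, y)
    expect_gte(lin$r_squared, 0)
    expect_lte(lin$r_squared, 1)
  }
})

test_that("fixation contrast orders fits by R-squared", {
  x <- seq(0, 23, length.out = 30)
  set.seed(35)
  good <- fit_exponential(x, 2041 * exp(-0.1519 * x) *
                            exp(stats::rnorm(30, sd = 0.2)))
  poor <- fit_exponential(x, 491.6 * exp(-0.1399 * x) *
                            exp(stats::rnorm(30, sd = 1.5)))
  ctr <- fixation_contrast(good, poor, labels = c("large", "small"))
  expect_equal(ctr$better, "large")
  expect_gt(ctr$delta_r_squared, 0)
  tie <- fixation_contrast(good, good)
  expect_equal(tie$better, "tie")
})

test_that("the variance-ratio F-test matches its closed form", {
  mkfit <- function(res) {
    structure(list(residuals = res), class = "bims_linear_fit")
  }
  same <- mkfit(c(-1, 0, 1, 2, -2))
  ft <- compare_fits_ftest(same, same)
  expect_equal(ft$f_statistic, 1)
  expect_equal(ft$p_value, 1)

  set.seed(36)
  ra <- stats::rnorm(50, sd = 2)   # variance 4
  rb <- stats::rnorm(50, sd = 1)   # variance 1
  ft2 <- compare_fits_ftest(mkfit(ra), mkfit(rb))
  expect_equal(ft2$df, c(48, 48))
  expect_equal(
    ft2$p_value,
    2 * stats::pf(ft2$f_statistic, 48, 48, lower.tail = FALSE),
    tolerance = 1e-12
  )
  expect_lt(ft2$p_value, 0.01)
  # order of arguments does not matter
  ft3 <- compare_fits_ftest(mkfit(rb), mkfit(ra))
  expect_equal(ft3$f_statistic, ft2$f_statistic)
  expect_equal(ft3$p_value, ft2$p_value)
})

test_that("F-test p-values are uniform under the null", {
  set.seed(37)
  mkfit <- function(res) {
    structure(list(residuals = res), class = "bims_linear_fit")
  }
  ps <- replicate(1000, {
    compare_fits_ftest(mkfit(stats::rnorm(30)), mkfit(stats::rnorm(30)))$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the logarithmic depth calibration recovers its generating constants", {
  pe <- exp(seq(log(100), log(2000), length.out = 30))
  id <- -7.7 * log(pe / 1532)
  cal <- calibrate_depth(pe, id)
  expect_equal(cal$a, -7.7, tolerance = 1e-8)
  expect_equal(cal$b, 1532, tolerance = 1e-4)
  expect_equal(cal$r_squared, 1, tolerance = 1e-10)
  # at PE = b the predicted depth is zero
  expect_equal(predict_depth(cal, cal$b), 0, tolerance = 1e-8)
  expect_error(predict_depth(cal, -5), "positive")
})

test_that("calibration validates its inputs", {
  expect_message(
    cal <- calibrate_depth(c(100, -5, 200, 400), c(10, 3, 5, 1)),
    "non-positive"
  )
  expect_equal(cal$n, 3)
  expect_error(suppressMessages(calibrate_depth(c(1, -1, -2), 1:3)),
               "at least 3")
  expect_error(calibrate_depth(rep(100, 5), 1:5), "zero variance")
})

test_that("depth is recoverable to ~2 mm from a clean band-2 energy track", {
  nf <- noiseless_fixated()
  pk <- nf$peaks
  b2 <- pk[pk$band_id == 2 & !pk$missing, ]
  depth <- nf$sim$depth_table$depth_mm[b2$blow_index]
  cal <- calibrate_depth(b2$peak_energy, depth)
  rmse <- sqrt(mean((predict_depth(cal, b2$peak_energy) - depth)^2))
  expect_lt(rmse, 2)
})
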