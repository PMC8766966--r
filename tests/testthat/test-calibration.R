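test_that("noiseless quadratic and linear responses are recovered exactly", {
  levels <- build_calibration_levels(100, 9)
  y <- 1000 * levels - 0.5 * levels^2        # monotone on [0, 100]
  for (w in c("1/x", "1/x2", "none")) {
    fit <- fit_calibration(calibration_points(levels, y), weighting = w)
    expect_equal(fit$a, 1000, tolerance = 1e-9)
    expect_equal(fit$b, -0.5, tolerance = 1e-9)
    expect_equal(fit$r2, 1, tolerance = 1e-12)
  }
  lin <- fit_calibration(calibration_points(levels, 2 * levels))
  expect_equal(lin$a, 2, tolerance = 1e-9)
  expect_lt(abs(lin$b), 1e-9)
})

test_that("coefficients match the independent normal-equation oracle", {
  # fixed 3-point example
  pts <- calibration_points(c(1, 2, 4), c(2, 5, 14))
  fit <- fit_calibration(pts, weighting = "1/x")
  oracle <- oracle_wls_fit(c(1, 2, 4), c(2, 5, 14), 1 / c(1, 2, 4))
  expect_equal(c(fit$a, fit$b), oracle, tolerance = 1e-10)
  # randomized noisy cases, all weighting schemes
  set.seed(11)
  levels <- build_calibration_levels(250, 9)
  for (i in 1:20) {
    a <- runif(1, 10, 2000)
    b <- runif(1, -0.3, 0.3) * a / 250
    y <- (a * levels + b * levels^2) * exp(rnorm(9, 0, 0.05))
    for (w in c("1/x", "1/x2", "none")) {
      fit <- fit_calibration(calibration_points(levels, y), weighting = w)
      oracle <- oracle_wls_fit(levels, y, calib_weights_for_test(levels, w))
      expect_equal(c(fit$a, fit$b), oracle, tolerance = 1e-8)
    }
  }
})

test_that("the fit is invariant to uniform rescaling of the weights", {
  levels <- build_calibration_levels(100, 9)
  set.seed(4)
  y <- (50 * levels - 0.05 * levels^2) * exp(rnorm(9, 0, 0.03))
  f1 <- fit_calibration(calibration_points(levels, y, weight = 1 / levels))
  f2 <- fit_calibration(calibration_points(levels, y, weight = 7 / levels))
  expect_equal(c(f1$a, f1$b, f1$r2), c(f2$a, f2$b, f2$r2), tolerance = 1e-12)
})

test_that("weighted r2 matches a direct evaluation of its formula", {
  levels <- build_calibration_levels(100, 9)
  set.seed(7)
  y <- (1000 * levels - 0.5 * levels^2) * exp(rnorm(9, 0, 0.05))
  fit <- fit_calibration(calibration_points(levels, y))
  w <- 1 / levels
  yhat <- fit$a * levels + fit$b * levels^2
  ybar <- sum(w * y) / sum(w)
  expect_equal(fit$r2, 1 - sum(w * (y - yhat)^2) / sum(w * (y - ybar)^2),
               tolerance = 1e-12)
  expect_equal(r_squared(fit), fit$r2, tolerance = 1e-12)
})

test_that("r2 is undefined when responses carry no variance", {
  levels <- c(1, 2, 4)
  fit <- fit_calibration(calibration_points(levels, 2 * levels))
  flat <- calibration_points(levels, c(5, 5, 5))
  expect_error(r_squared(fit, flat), class = "tdm_undefined_r2")
})

test_that("inverse prediction inverts the forward model on the whole range", {
  levels <- build_calibration_levels(100, 9)
  fit <- fit_calibration(calibration_points(levels, 1000 * levels - 0.5 * levels^2),
                         lod = 0.2)
  # spec'd point check against an independent bisection oracle
  y100 <- 1000 * 100 - 0.5 * 100^2
  expect_equal(inverse_predict(fit, y100)$conc, 100, tolerance = 1e-9)
  expect_equal(inverse_predict(fit, y100)$conc,
               oracle_invert(fit$a, fit$b, y100, 2 * fit$uloq), tolerance = 1e-9)
  # round-trip identity across the quantification range
  cc <- exp(seq(log(fit$lloq), log(fit$uloq), length.out = 41))
  yy <- fit$a * cc + fit$b * cc^2
  expect_equal(inverse_predict(fit, yy)$conc, cc, tolerance = 1e-9)
})

test_that("linear inversion and result qualifiers follow the limit conventions", {
  levels <- build_calibration_levels(10, 9)       # lloq 0.0390625
  fit <- fit_calibration(calibration_points(levels, 2 * levels), lod = 0.02)
  expect_equal(inverse_predict(fit, 10)$conc, 5)
  out <- inverse_predict(fit, c(0, 2 * 0.01, 2 * 0.03, 2 * fit$lloq, 2 * 5, 2 * 12))
  expect_equal(out$qualifier,
               c("below_lod", "below_lod", "below_lloq", "quantified",
                 "quantified", "above_uloq"))
  expect_equal(out$conc[[1]], 0)
  # exactly the LLOQ quantifies; exactly the LOD is detected
  expect_equal(inverse_predict(fit, 2 * fit$lloq)$qualifier, "quantified")
  expect_equal(inverse_predict(fit, 2 * 0.02)$qualifier, "below_lloq")
})

test_that("degenerate fits and out-of-model responses raise classed errors", {
  expect_error(fit_calibration(calibration_points(c(1, 1, 2), c(1, 1.1, 2))),
               class = "tdm_underdetermined")
  # turns over inside the range: a + 2 b uloq < 0 while all responses stay positive
  levels <- build_calibration_levels(100, 9)
  expect_error(fit_calibration(calibration_points(levels, 1000 * levels - 6 * levels^2)),
               class = "tdm_rejected_curve")
  fit <- fit_calibration(calibration_points(build_calibration_levels(100, 9),
                                            1000 * build_calibration_levels(100, 9) -
                                              0.5 * build_calibration_levels(100, 9)^2))
  # beyond the apex of the saturating curve
  expect_error(inverse_predict(fit, 1e9), class = "tdm_out_of_model")
  expect_error(inverse_predict(fit, -1), class = "tdm_invalid_response")
})

test_that("back-calculation reports the per-level percent deviation", {
  levels <- build_calibration_levels(10, 9)
  fit <- fit_calibration(calibration_points(levels, 2 * levels))
  clean <- back_calculate(fit)
  expect_equal(clean$deviation_pct, rep(0, 9), tolerance = 1e-9)
  bumped <- calibration_points(levels, 2 * levels * c(rep(1, 8), 1.1))
  dev <- back_calculate(fit, bumped)$deviation_pct
  expect_equal(dev[[9]], 10, tolerance = 1e-9)
  expect_equal(dev[1:8], rep(0, 8), tolerance = 1e-9)
})

test_that("synthetic 9-level curves at 5% proportional noise keep r2 near 1", {
  levels <- build_calibration_levels(3000, 9)
  a <- 1000; b <- -0.1 * a / 3000
  set.seed(23)
  r2 <- replicate(200, {
    y <- (a * levels + b * levels^2) * exp(rnorm(9, 0, 0.05))
    fit_calibration(calibration_points(levels, y))$r2
  })
  expect_gte(mean(r2 >= 0.996), 0.95)
})
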