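test_that("binning follows the half-open 50 mm convention anchored at 0", {
  tab <- pixel_table(map_mm = c(60, 70, 120),
                     resistance = c(1, 2, 6))
  pr <- bin_by_map(tab, "resistance", width = 50, n_min = 1)
  expect_equal(pr$bin_lo, c(50, 100))
  expect_equal(pr$mean, c(1.5, 6))
  expect_equal(pr$n, c(2L, 1L))

  ## MAP values spanning 100-499 give 8 bins
  tab2 <- pixel_table(map_mm = seq(100, 499, length.out = 200),
                      resistance = 1)
  expect_equal(nrow(bin_by_map(tab2, "resistance", n_min = 1)), 8L)

  ## a boundary value falls in the right-hand bin
  tab3 <- pixel_table(map_mm = 150, resistance = 3)
  pr3 <- bin_by_map(tab3, "resistance", n_min = 1)
  expect_equal(pr3$bin_lo, 150)
  expect_equal(pr3$bin_hi, 200)
})

test_that("binning conserves pixels and drops thin bins", {
  set.seed(1)
  tab <- pixel_table(map_mm = runif(500, 40, 500), resistance = rnorm(500))
  pr <- bin_by_map(tab, "resistance", n_min = 25)
  all_bins <- attr(pr, "all_bins")
  expect_equal(sum(all_bins$n), attr(pr, "n_valid"))
  expect_true(all(pr$n >= 25))
  expect_error(bin_by_map(pixel_table(numeric(0)), "resistance"),
               "zero valid pixels")
  ## invalid pixels are never binned
  tab$valid[1:250] <- FALSE
  pr2 <- bin_by_map(tab, "resistance", n_min = 1)
  expect_equal(sum(attr(pr2, "all_bins")$n), 250L)
})

test_that("rain-reduction subset uses a closed interval on valid pixels", {
  tab <- pixel_table(map_mm = 100,
                     rain_reduction = c(0.04, 0.05, 0.07, 0.10, 0.11))
  expect_equal(nrow(subset_by_rain_reduction(tab)), 3L)
  expect_equal(nrow(subset_by_rain_reduction(tab, 0, 1)), 5L)
  expect_error(subset_by_rain_reduction(tab, 0.2, 0.1), "lo")
  tab$valid <- FALSE
  expect_equal(nrow(subset_by_rain_reduction(tab, 0, 1)), 0L)
})

test_that("exact linear bin means select the linear family with R2 = 1", {
  x <- seq(25, 475, by = 50)
  fs <- suppressWarnings(fit_candidates(make_profile(x, 1 + 0.002 * x)))
  expect_equal(fs$selected, "linear")
  expect_equal(fs$fits$linear$r2, 1, tolerance = 1e-9)
  expect_lt(fs$gate_p, 0.05)
  expect_equal(unname(coef(fs)[2]), 0.002, tolerance = 1e-9)
})

test_that("exact quadratic bin means fail the linear gate and select quadratic", {
  x <- seq(25, 475, by = 50)
  y <- -(x - 250)^2 / 1e4 + 5
  fs <- suppressWarnings(fit_candidates(make_profile(x, y)))
  expect_gt(fs$gate_p, 0.05)
  expect_equal(fs$selected, "quadratic")   # ties with cubic -> fewer params
  expect_equal(fs$fits$quadratic$r2, 1, tolerance = 1e-9)
  expect_gte(fs$fits$quadratic$r2 + 1e-9,
             max(vapply(fs$fits, `[[`, numeric(1), "r2")))
  expect_equal(peak_of_fit(fs), 250, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("too few bins is a hard error", {
  x <- c(25, 75, 125, 175)
  expect_error(fit_candidates(make_profile(x, x)), "insufficient bins")
})

test_that("exponential data is recovered by the exponential candidate", {
  x <- seq(25, 475, by = 50)
  y <- 2 * exp(-0.004 * x)
  fs <- suppressWarnings(fit_candidates(make_profile(x, y)))
  expect_equal(unname(coef(fs$fits$exponential)[["a"]]), 2, tolerance = 1e-6)
  expect_equal(unname(coef(fs$fits$exponential)[["b"]]), -0.004,
               tolerance = 1e-6)
  expect_equal(fs$fits$exponential$r2, 1, tolerance = 1e-9)
})

test_that("polynomial R2 is invariant to an affine rescaling of the MAP axis", {
  set.seed(3)
  x <- seq(25, 475, by = 50)
  y <- 1 + 0.01 * x - 2e-5 * x^2 + rnorm(length(x), 0, 0.05)
  f1 <- suppressWarnings(fit_candidates(make_profile(x, y)))
  f2 <- suppressWarnings(fit_candidates(make_profile(2 * x + 100, y)))
  for (fam in c("linear", "quadratic", "cubic"))
    expect_equal(f1$fits[[fam]]$r2, f2$fits[[fam]]$r2, tolerance = 1e-8)
})

test_that("peak_of_fit matches a dense-grid argmax and flags boundaries", {
  x <- seq(25, 475, by = 50)
  ## cubic with an interior maximum
  y <- 1 + 0.02 * x - 6e-5 * x^2 + 5e-8 * x^3
  fs <- suppressWarnings(fit_candidates(make_profile(x, y)))
  cub <- fs$fits$cubic
  pk <- peak_of_fit(cub, domain = c(25, 475))
  grid <- seq(25, 475, by = 0.001)
  dense <- grid[which.max(predict(cub, newdata = grid))]
  expect_equal(as.numeric(pk), dense, tolerance = 1e-2)
  expect_false(attr(pk, "boundary"))

  ## monotone cubic peaks at the domain boundary
  ym <- 1 + 0.002 * x + 1e-9 * x^3
  fsm <- suppressWarnings(fit_candidates(make_profile(x, ym)))
  pkm <- peak_of_fit(fsm$fits$cubic, domain = c(25, 475))
  expect_equal(as.numeric(pkm), 475)
  expect_true(attr(pkm, "boundary"))

  expect_error(peak_of_fit(fs$fits$linear), "no interior peak")
})

test_that("confidence bands contain the fitted curve", {
  set.seed(9)
  x <- seq(25, 475, by = 50)
  y <- 1 + 0.004 * x + rnorm(length(x), 0, 0.1)
  fs <- suppressWarnings(fit_candidates(make_profile(x, y)))
  xx <- seq(50, 450, by = 50)
  ci <- predict(fs$fits$linear, newdata = xx, interval = "confidence")
  expect_true(all(ci[, "lwr"] <= ci[, "fit"] & ci[, "fit"] <= ci[, "upr"]))
  ## exponential band via the seeded bootstrap is reproducible
  ye <- 2 * exp(-0.004 * x) * (1 + rnorm(length(x), 0, 0.02))
  fe <- suppressWarnings(fit_candidates(make_profile(x, ye)))
  c1 <- predict(fe$fits$exponential, newdata = xx, interval = "confidence",
                nboot = 100, seed = 5)
  c2 <- predict(fe$fits$exponential, newdata = xx, interval = "confidence",
                nboot = 100, seed = 5)
  expect_identical(c1, c2)
  expect_true(all(c1[, "lwr"] <= c1[, "fit"] + 1e-9))
})
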