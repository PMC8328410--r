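test_that("scalar reduction metrics follow their definitions and contracts", {
  expect_equal(rain_reduction(300, 270), 0.10)
  expect_equal(rain_reduction(200, 200), 0.0)
  expect_equal(rain_reduction(250, 275), -0.10)
  expect_error(rain_reduction(0, 10), "positive")

  expect_equal(ndvi_reduction(0.40, 0.38), 0.05)
  expect_equal(ndvi_reduction(0.30, 0.30), 0.0)
  expect_equal(ndvi_reduction(0.25, 0.26), -0.04)
  expect_true(is.na(ndvi_reduction(0, 0.1)))     # bare ground, not an error
  expect_true(is.na(ndvi_reduction(-0.05, 0.1)))

  expect_equal(resistance(0.10, 0.05), 2.0)
  expect_equal(resistance(0.08, 0.08), 1.0)
  expect_equal(resistance(0.06, 0.01), 6.0)
  expect_error(resistance(-0.02, 0.05), "rain_red")
  expect_error(resistance(0.05, 0.005), "below")

  expect_equal(resilience(0.30, 0.30), 1.0)
  expect_equal(resilience(0.24, 0.30), 0.8)
  expect_equal(resilience(0.33, 0.5, 0.30, denominator = "dry"), 1.1)
  expect_true(is.na(resilience(0.3, 0)))
  expect_error(resilience(0.3, 0.4, denominator = "dry"), "n_dry")
})

## build co-registered cubes whose period means equal the given matrices
cubes_from_period_means <- function(pn, pd, nn, nd, np, grid) {
  mk <- function(a, b, c, type) {
    v <- array(NA_real_, c(grid$nrow, grid$ncol, 3))
    v[, , 1] <- a; v[, , 2] <- b; v[, , 3] <- c
    grid_cube(v, 2000:2002, grid, type = type)
  }
  list(precip = mk(pn, pd, pd, "unknown"), ndvi = mk(nn, nd, np, "unknown"),
       part = structure(list(normal_years = 2000L, dry_years = 2001L,
                             recovery_years = 2002L, mode = "explicit"),
                        class = "period_partition"))
}

test_that("compute_pixel_metrics composes the scalar metrics per pixel", {
  g <- grid_spec(1, 1, xmin = 100, ymax = 44, cellsize = 0.5)
  x <- cubes_from_period_means(300, 270, 0.40, 0.38, 0.40, g)
  m <- compute_pixel_metrics(x$precip, x$ndvi, x$part)
  expect_equal(as.numeric(m$rain_reduction), 0.10)
  expect_equal(as.numeric(m$ndvi_reduction), 0.05)
  expect_equal(as.numeric(m$resistance), 2.0)
  expect_equal(as.numeric(m$resilience), 1.0)
  expect_true(m$valid[1, 1])
  expect_equal(m$exclusion_reason[1, 1], "none")

  ## sub-threshold NDVI response is excluded with its reason recorded
  y <- cubes_from_period_means(300, 270, 0.40, 0.398, 0.40, g)
  m2 <- compute_pixel_metrics(y$precip, y$ndvi, y$part)
  expect_false(m2$valid[1, 1])
  expect_equal(m2$exclusion_reason[1, 1], "ndvi_reduction_below_min")
  expect_true(is.na(m2$resistance[1, 1]))
})

test_that("filter audit on a 3x3 toy matches hand enumeration", {
  g <- grid_spec(3, 3, xmin = 100, ymax = 44, cellsize = 0.5)
  pn <- matrix(300, 3, 3); pd <- matrix(270, 3, 3)
  nn <- matrix(0.40, 3, 3); nd <- matrix(0.36, 3, 3); np <- matrix(0.38, 3, 3)
  ## pixel (1,1): wetter dry period  -> no_rain_reduction
  pd[1, 1] <- 310
  ## pixel (2,2): NDVI reduction 0.5% -> ndvi_reduction_below_min
  nd[2, 2] <- 0.398
  ## pixel (3,3): bare ground        -> nodata
  nn[3, 3] <- 0
  ## pixel (1,3): missing NDVI       -> nodata
  np[1, 3] <- NA
  x <- cubes_from_period_means(pn, pd, nn, nd, np, g)
  m <- compute_pixel_metrics(x$precip, x$ndvi, x$part)
  counts <- exclusion_counts(m)
  expect_equal(as.integer(counts[["none"]]), 5L)
  expect_equal(as.integer(counts[["nodata"]]), 2L)
  expect_equal(as.integer(counts[["no_rain_reduction"]]), 1L)
  expect_equal(as.integer(counts[["ndvi_reduction_below_min"]]), 1L)
  ## no valid pixel violates the filters
  expect_true(all(m$rain_reduction[m$valid] > 0))
  expect_true(all(m$ndvi_reduction[m$valid] >= 0.01))
})

test_that("metrics are invariant to NDVI rescaling", {
  g <- grid_spec(4, 4, xmin = 100, ymax = 44, cellsize = 0.5)
  set.seed(42)
  pn <- matrix(runif(16, 100, 500), 4, 4)
  pd <- pn * (1 - runif(16, 0.02, 0.3))
  nn <- matrix(runif(16, 0.2, 0.8), 4, 4)
  nd <- nn * (1 - runif(16, 0.02, 0.3))
  np <- nn * runif(16, 0.7, 1.1)
  x <- cubes_from_period_means(pn, pd, nn, nd, np, g)
  m1 <- compute_pixel_metrics(x$precip, x$ndvi, x$part)
  cc <- 0.5
  x2 <- cubes_from_period_means(pn, pd, cc * nn, cc * nd, cc * np, g)
  m2 <- compute_pixel_metrics(x2$precip, x2$ndvi, x2$part)
  expect_equal(m1$ndvi_reduction, m2$ndvi_reduction)
  expect_equal(m1$resistance, m2$resistance)
  expect_equal(m1$resilience, m2$resilience)
  expect_identical(m1$valid, m2$valid)
})

test_that("grid path equals element-wise scalar application bit-for-bit", {
  g <- grid_spec(6, 6, xmin = 100, ymax = 44, cellsize = 0.5)
  set.seed(7)
  pn <- matrix(runif(36, 100, 500), 6, 6)
  pd <- pn * (1 - runif(36, 0.02, 0.3))
  nn <- matrix(runif(36, 0.2, 0.8), 6, 6)
  nd <- nn * (1 - runif(36, 0.02, 0.3))
  np <- nn * runif(36, 0.7, 1.1)
  x <- cubes_from_period_means(pn, pd, nn, nd, np, g)
  m <- compute_pixel_metrics(x$precip, x$ndvi, x$part)
  expect_identical(as.vector(m$rain_reduction),
                   as.vector(rain_reduction(pn, pd)))
  expect_identical(as.vector(m$ndvi_reduction),
                   as.vector(ndvi_reduction(nn, nd)))
  expect_identical(as.vector(m$resistance)[as.vector(m$valid)],
                   as.vector(rain_reduction(pn, pd) /
                               ndvi_reduction(nn, nd))[as.vector(m$valid)])
  expect_identical(as.vector(m$resilience),
                   as.vector(resilience(np, nn)))
})

test_that("both resilience conventions are reported and selectable", {
  g <- grid_spec(1, 1, xmin = 100, ymax = 44, cellsize = 0.5)
  x <- cubes_from_period_means(300, 270, 0.40, 0.30, 0.33, g)
  m_n <- compute_pixel_metrics(x$precip, x$ndvi, x$part,
                               resilience_denominator = "normal")
  m_d <- compute_pixel_metrics(x$precip, x$ndvi, x$part,
                               resilience_denominator = "dry")
  expect_equal(as.numeric(m_n$resilience), 0.33 / 0.40)
  expect_equal(as.numeric(m_d$resilience), 0.33 / 0.30)
  expect_equal(m_n$resilience_dry, m_d$resilience_dry)
})

test_that("mismatched grids are refused", {
  g1 <- grid_spec(2, 2, xmin = 100, ymax = 44, cellsize = 0.5)
  g2 <- grid_spec(2, 2, xmin = 101, ymax = 44, cellsize = 0.5)
  a <- cubes_from_period_means(300, 270, 0.4, 0.38, 0.4, g1)
  b <- cubes_from_period_means(300, 270, 0.4, 0.38, 0.4, g2)
  expect_error(compute_pixel_metrics(a$precip, b$ndvi, a$part),
               "co-registered")
})
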