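test_that("regional anomalies subtract the whole-series mean", {
  g <- small_grid(2)
  cst <- const_cube(c(5, 5, 5), 2000:2002, g)
  expect_true(all(abs(regional_anomaly(cst)$anomaly) < 1e-12))

  cube <- const_cube(c(100, 120, 80), 2000:2002, g)
  an <- regional_anomaly(cube)
  expect_equal(an$anomaly, c(0, 20, -20))
  expect_equal(attr(an, "baseline"), 100)
  expect_lt(abs(sum(an$anomaly)), 1e-9)
})

test_that("yearly means use valid pixels only", {
  g <- small_grid(2)
  v <- array(NA_real_, c(2, 2, 2))
  v[, , 1] <- matrix(c(10, 20, 30, 40), 2, 2)
  v[, , 2] <- matrix(c(8, NA, NA, 12), 2, 2)   # half the pixels missing
  cube <- grid_cube(v, 2000:2001, g)
  an <- regional_anomaly(cube)
  expect_equal(an$mean, c(25, 10))             # hand-computed on the toy
  expect_equal(an$anomaly, c(7.5, -7.5))

  v[, , 2] <- NA
  expect_error(regional_anomaly(grid_cube(v, 2000:2001, g)),
               "no valid pixels in year 2001")
})

test_that("auto partition finds the below-baseline run", {
  an <- anomaly_series(2001:2009, c(+1, +1, -1, -1, -1, -1, -1, +1, +1))
  p <- partition_years(an, "auto", min_run = 3)
  expect_equal(p$dry_years, 2003:2007)
  expect_equal(p$normal_years, 2001:2002)
  expect_equal(p$recovery_years, 2008:2009)

  ## a series with no below-baseline run at all
  expect_error(partition_years(anomaly_series(2001:2009, rep(1, 9)),
                               "auto", min_run = 3),
               "no dry period detected")

  ## two negative runs (lengths 4 and 6): the longer one is the dry period
  vals <- c(2, -1, -1, -1, -1, 3, 2, -1, -1, -1, -1, -1, -1, 4, 4)
  p2 <- partition_years(anomaly_series(1991:2005, vals), "auto", min_run = 3)
  expect_equal(p2$dry_years, 1998:2003)
  expect_equal(p2$normal_years, 1991:1997)

  ## a qualifying run touching the series start has no normal baseline
  expect_error(partition_years(anomaly_series(2001:2008,
                                              c(-1, -1, -1, -1, 1, 1, 1, 1)),
                               "auto", min_run = 3),
               "no normal baseline")
})

test_that("explicit and auto partitions agree when given the detected ranges", {
  an <- anomaly_series(1982:2013,
                       c(rep(0.5, 17), rep(-1, 13), rep(2, 2)))
  pa <- partition_years(an, "auto")
  pe <- partition_years(an, "explicit", normal = 1982:1998,
                        dry = 1999:2011, recovery = 2012:2013)
  expect_equal(pa$dry_years, pe$dry_years)
  expect_equal(pa$normal_years, pe$normal_years)
  expect_equal(pa$recovery_years, pe$recovery_years)

  expect_error(partition_years(an, "explicit", normal = 1982:1999,
                               dry = 1999:2011, recovery = 2012:2013),
               "overlap")
  expect_error(partition_years(an, "explicit", normal = 1982:1997,
                               dry = 1999:2011, recovery = 2012:2013),
               "cover")
})

test_that("period_stats computes the regional deficit on the stated convention", {
  g <- small_grid(2)
  ## all-years regional mean 300, dry-years mean 265.5 -> deficit 11.5%
  yearly <- c(rep(334.5, 10), rep(265.5, 10))
  cube <- const_cube(yearly, 1991:2010, g)
  part <- partition_years(regional_anomaly(cube), "explicit",
                          normal = 1991:2000, dry = 2001:2008,
                          recovery = 2009:2010)
  ## dry period 2001-2008 and recovery both sit at 265.5
  st <- period_stats(cube, part)
  expect_equal(st$regional$all, 300)
  expect_equal(st$regional$deficit_pct, 11.5)

  ## equal dry and normal means give a deficit with the documented sign
  cube2 <- const_cube(rep(200, 8), 2001:2008, g)
  part2 <- partition_years(regional_anomaly(cube2), "explicit",
                           normal = 2001:2004, dry = 2005:2007,
                           recovery = 2008)
  expect_equal(period_stats(cube2, part2)$regional$deficit_pct, 0)
})

test_that("per-pixel period means match brute-force on a toy cube", {
  g <- grid_spec(1, 3, xmin = 100, ymax = 44, cellsize = 0.5)
  v <- array(NA_real_, c(1, 3, 4))
  v[1, , 1] <- c(1, 10, 100); v[1, , 2] <- c(3, 30, 300)
  v[1, , 3] <- c(5, 50, 500); v[1, , 4] <- c(7, 70, 700)
  cube <- grid_cube(v, 2001:2004, g)
  part <- partition_years(regional_anomaly(cube), "explicit",
                          normal = 2001:2002, dry = 2003, recovery = 2004)
  st <- period_stats(cube, part)
  expect_equal(as.numeric(st$pixel$normal), c(2, 20, 200))
  expect_equal(as.numeric(st$pixel$dry), c(5, 50, 500))
  expect_equal(as.numeric(st$pixel$recovery), c(7, 70, 700))
  expect_error(period_stats(cube, structure(list(normal_years = 2001:2002,
                                                 dry_years = 2003:2005,
                                                 recovery_years = integer(0)),
                                            class = "period_partition")),
               "not in cube")
})

test_that("auto partition recovers an injected dry run under noise", {
  ## 32-year series, 13-year injected deficit, small regional noise
  hits <- vapply(1:100, function(s) {
    set.seed(s + 4000)
    yearly <- c(rep(1.049, 17), rep(0.885, 13), rep(1.331, 2)) *
      (1 + rnorm(32, 0, 0.02)) * 300
    p <- tryCatch(partition_years(anomaly_series(1982:2013, yearly), "auto"),
                  error = function(e) NULL)
    !is.null(p) && identical(p$dry_years, 1999:2011)
  }, logical(1))
  expect_gte(sum(hits), 95)
})
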