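## Shared fixtures built in code.

small_grid <- function(n = 4) grid_spec(n, n, xmin = 100, ymax = 44,
                                        cellsize = 0.5)

## A grid_cube with given per-year constant values (or a function of year
## index returning a matrix)
const_cube <- function(vals_by_year, years, grid = small_grid(),
                       type = "unknown") {
  v <- array(NA_real_, c(grid$nrow, grid$ncol, length(years)))
  for (k in seq_along(years)) {
    x <- if (is.function(vals_by_year)) vals_by_year(k) else vals_by_year[k]
    v[, , k] <- x
  }
  grid_cube(v, years, grid, type = type)
}

## Build a binned_profile directly from bin mids and means (for fitting
## tests that bypass pixel binning)
make_profile <- function(bin_mid, mean, n = 100L, sd = 0,
                         response = "response", width = 50) {
  d <- data.frame(bin_lo = bin_mid - width / 2, bin_hi = bin_mid + width / 2,
                  bin_mid = bin_mid, n = n, mean = mean, sd = sd)
  attr(d, "response") <- response
  attr(d, "width") <- width
  attr(d, "n_valid") <- sum(n)
  class(d) <- c("binned_profile", "data.frame")
  d
}

## Pixel table in the shape bin_by_map()/subset_by_rain_reduction() expect
pixel_table <- function(map_mm, resistance = NA_real_,
                        resilience = NA_real_, rain_reduction = NA_real_,
                        valid = TRUE) {
  n <- max(length(map_mm), length(resistance), length(resilience),
           length(rain_reduction))
  if (length(map_mm) == 0L) n <- 0L
  data.frame(map_mm = rep_len(map_mm, n),
             resistance = rep_len(resistance, n),
             resilience = rep_len(resilience, n),
             rain_reduction = rep_len(rain_reduction, n),
             valid = rep_len(valid, n))
}

## Random station table over a bounding box; values from value_fn(lon, lat)
random_stations <- function(n, years, value_fn, seed = 1,
                            lon_range = c(100, 110), lat_range = c(38, 44)) {
  set.seed(seed)
  lon <- runif(n, lon_range[1], lon_range[2])
  lat <- runif(n, lat_range[1], lat_range[2])
  df <- do.call(rbind, lapply(years, function(y)
    data.frame(station_id = sprintf("S%02d", seq_len(n)), lon = lon,
               lat = lat, year = y, precip_mm = value_fn(lon, lat, y))))
  station_table(df)
}
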