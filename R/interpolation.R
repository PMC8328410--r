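#' Read a station annual-precipitation table
#'
#' Expects a UTF-8 CSV with header columns `station_id, lon, lat, year,
#' precip_mm` (one row per station-year).
#'
#' @param path CSV path.
#' @return A `data.frame` of class `station_table`.
#' @export
read_stations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lon", "lat", "year", "precip_mm")
  if (!all(need %in% names(df)))
    stop_("station CSV must have columns %s", paste(need, collapse = ", "))
  station_table(df)
}

#' Construct/validate a station table
#'
#' @param df Data frame with columns `station_id, lon, lat, year, precip_mm`.
#' @export
station_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (any(!is.finite(df$lon)) || any(!is.finite(df$lat)))
    stop_("non-finite station coordinates")
  if (any(df$precip_mm < 0, na.rm = TRUE))
    stop_("negative precipitation in station records")
  ## one (lon, lat) per station id
  loc <- unique(df[, c("station_id", "lon", "lat")])
  if (anyDuplicated(loc$station_id))
    stop_("station id with conflicting coordinates: %s",
          loc$station_id[duplicated(loc$station_id)][1])
  df$year <- as.integer(df$year)
  class(df) <- c("station_table", "data.frame")
  df
}

#' Fit a thin-plate smoothing spline to one year of station data
#'
#' Fits a full-rank 2-D thin-plate smoothing spline in (lon, lat) to the
#' stations reporting in `year`. With `smoothing = 0` the surface
#' interpolates the station values exactly; with `smoothing = "gcv"` the
#' penalty is chosen by generalized cross-validation. As the penalty grows
#' the surface tends to the best-fit affine plane (the null space of the
#' thin-plate penalty).
#'
#' @param stations A [station_table()].
#' @param year Calendar year to fit.
#' @param smoothing Non-negative smoothing parameter, or `"gcv"`.
#' @return An object of class `tps_surface` with a [predict()] method.
#' @export
tps_fit <- function(stations, year, smoothing = "gcv") {
  stopifnot(inherits(stations, "station_table"))
  d <- stations[stations$year == year & !is.na(stations$precip_mm), ]
  if (nrow(d) < 4L)
    stop_("year %d: %d usable stations, need at least 4", year, nrow(d))
  if (qr(cbind(1, d$lon, d$lat))$rank < 3L)
    stop_("year %d: stations are collinear", year)
  k <- nrow(d)  # full rank: spline basis spans all station locations
  dat <- data.frame(y = d$precip_mm, lon = d$lon, lat = d$lat)
  fit <- if (identical(smoothing, "gcv")) {
    mgcv::gam(y ~ s(lon, lat, bs = "tp", k = k), data = dat,
              method = "GCV.Cp")
  } else {
    stopifnot(is_scalar_number(smoothing), smoothing >= 0)
    mgcv::gam(y ~ s(lon, lat, bs = "tp", k = k), data = dat, sp = smoothing)
  }
  structure(list(gam = fit, year = year, n_stations = k,
                 smoothing = smoothing, sp = unname(fit$sp)),
            class = "tps_surface")
}

#' @export
print.tps_surface <- function(x, ...) {
  cat(sprintf("<tps_surface> year %d, %d stations, penalty %s (sp = %.4g)\n",
              x$year, x$n_stations,
              if (identical(x$smoothing, "gcv")) "GCV" else "fixed", x$sp))
  invisible(x)
}

#' Evaluate a fitted thin-plate spline surface
#'
#' @param object A `tps_surface`.
#' @param lon,lat Coordinates at which to evaluate (recycled pairwise).
#' @param ... Unused.
#' @export
predict.tps_surface <- function(object, lon, lat, ...) {
  as.numeric(predict(object$gam, newdata = data.frame(lon = lon, lat = lat)))
}

#' Interpolate station precipitation to a grid, one surface per year
#'
#' Fits [tps_fit()] per year over the station table's full year range and
#' evaluates each surface at the grid pixel centers. Negative evaluations
#' (possible spline overshoot) are clamped to 0 mm.
#'
#' @param stations A [station_table()].
#' @param target A [grid_spec()] (or `grid_cube`).
#' @param smoothing Passed to [tps_fit()].
#' @param years Years to interpolate (default: all years present).
#' @return A [grid_cube()] of annual precipitation (mm/yr).
#' @export
interpolate_precip <- function(stations, target, smoothing = "gcv",
                               years = NULL) {
  if (inherits(target, "grid_cube")) target <- target$grid
  stopifnot(inherits(target, "grid_spec"))
  years <- sort(unique(as.integer(years %||% stations$year)))
  check_years_gapless(years)
  lon <- grid_lon(target); lat <- grid_lat(target)
  if (max(stations$lon) < min(lon) || min(stations$lon) > max(lon) ||
      max(stations$lat) < min(lat) || min(stations$lat) > max(lat))
    stop_("target grid does not overlap the station bounding box")
  pts <- expand.grid(lat = lat, lon = lon)  # lat fastest = column-major
  out <- array(NA_real_, c(target$nrow, target$ncol, length(years)))
  for (k in seq_along(years)) {
    surf <- tps_fit(stations, years[k], smoothing = smoothing)
    v <- predict(surf, lon = pts$lon, lat = pts$lat)
    out[, , k] <- matrix(pmax(v, 0), target$nrow, target$ncol)
  }
  grid_cube(out, years, target, type = "precip")
}
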