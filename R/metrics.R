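#' Relative precipitation reduction in a dry period
#'
#' `(p_normal - p_dry) / p_normal`: the fractional drop of the dry-period
#' mean annual precipitation below the normal-period mean. May be negative
#' (a wetter-than-normal "dry" period); negativity is handled by the pixel
#' validity filter downstream, not here.
#'
#' @param p_normal,p_dry Normal- and dry-period mean annual precipitation
#'   (mm/yr); vectorized.
#' @return Fractional reduction (positive = drier).
#' @export
rain_reduction <- function(p_normal, p_dry) {
  if (any(p_normal <= 0, na.rm = TRUE))
    stop_("p_normal must be positive")
  (p_normal - p_dry) / p_normal
}

#' Relative NDVI reduction in a dry period
#'
#' `(n_normal - n_dry) / n_normal`. Pixels with non-positive normal-period
#' NDVI are bare or sparsely vegetated and return `NA` (flagged as missing
#' downstream) rather than erroring.
#'
#' @param n_normal,n_dry Normal- and dry-period mean NDVI; vectorized.
#' @export
ndvi_reduction <- function(n_normal, n_dry) {
  out <- (n_normal - n_dry) / n_normal
  out[!is.na(n_normal) & n_normal <= 0] <- NA_real_
  out
}

#' Ecosystem resistance to a dry period
#'
#' Resistance = rain reduction / NDVI reduction: the NDVI response
#' normalized by the precipitation forcing each pixel actually
#' experienced. High resistance means vegetation declined proportionally
#' less than rainfall did. Only defined on pixels that passed the validity
#' filter (positive rain reduction, NDVI reduction at or above the
#' minimum); calling it on filtered-out inputs is a contract violation.
#'
#' @param rain_red,ndvi_red Fractional reductions (vectorized).
#' @param min_ndvi_reduction The filter threshold inputs must satisfy
#'   (default 0.01, i.e. the 1% NDVI-reduction exclusion).
#' @export
resistance <- function(rain_red, ndvi_red, min_ndvi_reduction = 0.01) {
  if (any(rain_red <= 0, na.rm = TRUE))
    stop_("resistance called with rain_red <= 0 (filtered-out pixel)")
  if (any(ndvi_red < min_ndvi_reduction, na.rm = TRUE))
    stop_("resistance called with ndvi_red below %g (filtered-out pixel)",
          min_ndvi_reduction)
  rain_red / ndvi_red
}

#' Ecosystem resilience after a dry period
#'
#' The ratio of recovery-period NDVI to a reference-period NDVI. The
#' default reference is the normal period; `denominator = "dry"` uses the
#' dry-period mean instead (the alternative convention in which resilience
#' measures the rebound from the depressed state). Non-positive
#' denominators give `NA`.
#'
#' @param n_post Recovery-period mean NDVI (vectorized).
#' @param n_normal,n_dry Reference-period mean NDVI.
#' @param denominator `"normal"` (default) or `"dry"`.
#' @export
resilience <- function(n_post, n_normal, n_dry = NULL,
                       denominator = c("normal", "dry")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "normal") n_normal else {
    if (is.null(n_dry)) stop_("denominator \"dry\" requires n_dry")
    n_dry
  }
  out <- n_post / den
  out[!is.na(den) & den <= 0] <- NA_real_
  out
}

#' Per-pixel dry-period response metrics
#'
#' Runs the full per-pixel procedure: period means of precipitation and
#' NDVI (`Pnormal`, `Pdry`, `NDVInormal`, `NDVIdry`, `NDVIpost`), mean
#' annual precipitation over the configured window, rain and NDVI
#' reductions, resistance, resilience (both denominator conventions are
#' reported), and the validity filter with an exclusion reason per pixel.
#'
#' Exclusion reasons, applied in order of precedence:
#' \describe{
#'   \item{`nodata`}{a required period mean is missing, `Pnormal <= 0`, or
#'     `NDVInormal <= 0` (bare/sparse vegetation).}
#'   \item{`no_rain_reduction`}{`rain_reduction <= 0`: the pixel saw no
#'     precipitation reduction, so a drought response is undefined.}
#'   \item{`ndvi_reduction_below_min`}{`ndvi_reduction <
#'     min_ndvi_reduction` (default 1%); screens pixels whose NDVI did not
#'     respond, e.g. under human disturbance.}
#' }
#' Resistance is computed only on valid pixels; resilience wherever its
#' denominator is positive.
#'
#' @param precip,ndvi Co-registered [grid_cube()]s covering all partition
#'   years.
#' @param part A [partition_years()] result with a non-empty recovery
#'   period.
#' @param min_ndvi_reduction Validity threshold on the NDVI reduction
#'   fraction (default 0.01).
#' @param resilience_denominator `"normal"` (default) or `"dry"`.
#' @param map_window Years defining per-pixel mean annual precipitation:
#'   `"all"` (default) or `"normal"`.
#' @return An object of class `pixel_metrics`: matrices `map_mm`,
#'   `p_normal`, `p_dry`, `ndvi_normal`, `ndvi_dry`, `ndvi_post`,
#'   `rain_reduction`, `ndvi_reduction`, `resistance`,
#'   `resilience_normal`, `resilience_dry`, `resilience`, logical `valid`,
#'   character `exclusion_reason`, plus the grid and settings.
#' @export
compute_pixel_metrics <- function(precip, ndvi, part,
                                  min_ndvi_reduction = 0.01,
                                  resilience_denominator = c("normal", "dry"),
                                  map_window = c("all", "normal")) {
  resilience_denominator <- match.arg(resilience_denominator)
  map_window <- match.arg(map_window)
  stopifnot(inherits(precip, "grid_cube"), inherits(ndvi, "grid_cube"),
            inherits(part, "period_partition"))
  if (!grids_equal(precip$grid, ndvi$grid))
    stop_("precipitation and NDVI cubes are not co-registered")
  if (!length(part$recovery_years))
    stop_("recovery period is empty: resilience undefined")

  p_normal <- period_mean(precip, part$normal_years)
  p_dry    <- period_mean(precip, part$dry_years)
  n_normal <- period_mean(ndvi, part$normal_years)
  n_dry    <- period_mean(ndvi, part$dry_years)
  n_post   <- period_mean(ndvi, part$recovery_years)
  map_mm <- if (map_window == "all") period_mean(precip, precip$years)
            else p_normal

  dims <- dim(p_normal)
  reason <- matrix("none", dims[1], dims[2])
  nodata <- is.na(p_normal) | is.na(p_dry) | is.na(n_normal) |
    is.na(n_dry) | is.na(n_post) | is.na(map_mm) |
    (!is.na(p_normal) & p_normal <= 0) | (!is.na(n_normal) & n_normal <= 0)
  reason[nodata] <- "nodata"

  rain_red <- matrix(NA_real_, dims[1], dims[2])
  ok <- !nodata
  rain_red[ok] <- rain_reduction(p_normal[ok], p_dry[ok])
  ndvi_red <- ndvi_reduction(n_normal, n_dry)
  ndvi_red[nodata] <- NA_real_

  no_rr <- !nodata & rain_red <= 0
  reason[no_rr] <- "no_rain_reduction"
  below <- !nodata & !no_rr & ndvi_red < min_ndvi_reduction
  reason[below] <- "ndvi_reduction_below_min"
  valid <- reason == "none"

  res <- matrix(NA_real_, dims[1], dims[2])
  res[valid] <- resistance(rain_red[valid], ndvi_red[valid],
                           min_ndvi_reduction = min_ndvi_reduction)

  resil_norm <- resilience(n_post, n_normal, denominator = "normal")
  resil_norm[nodata] <- NA_real_
  resil_dry <- resilience(n_post, n_normal, n_dry, denominator = "dry")
  resil_dry[nodata] <- NA_real_

  out <- list(map_mm = map_mm, p_normal = p_normal, p_dry = p_dry,
              ndvi_normal = n_normal, ndvi_dry = n_dry, ndvi_post = n_post,
              rain_reduction = rain_red, ndvi_reduction = ndvi_red,
              resistance = res,
              resilience_normal = resil_norm, resilience_dry = resil_dry,
              resilience = if (resilience_denominator == "normal")
                resil_norm else resil_dry,
              valid = valid, exclusion_reason = reason,
              grid = precip$grid, partition = part,
              settings = list(min_ndvi_reduction = min_ndvi_reduction,
                              resilience_denominator = resilience_denominator,
                              map_window = map_window))
  class(out) <- "pixel_metrics"
  out
}

#' @export
print.pixel_metrics <- function(x, ...) {
  tab <- exclusion_counts(x)
  cat(sprintf("<pixel_metrics> %d x %d pixels, %d valid\n",
              nrow(x$valid), ncol(x$valid), sum(x$valid)))
  cat("  exclusions:\n")
  for (nm in names(tab)) cat(sprintf("    %-26s %d\n", nm, tab[[nm]]))
  cat(sprintf("  resilience denominator: %s; MAP window: %s\n",
              x$settings$resilience_denominator, x$settings$map_window))
  invisible(x)
}

#' Tally of pixel exclusion reasons
#'
#' @param metrics A [compute_pixel_metrics()] result.
#' @return Named integer vector over all reason codes.
#' @export
exclusion_counts <- function(metrics) {
  stopifnot(inherits(metrics, "pixel_metrics"))
  lev <- c("none", "nodata", "no_rain_reduction", "ndvi_reduction_below_min")
  table(factor(metrics$exclusion_reason, levels = lev))
}

#' Per-pixel metric table
#'
#' Flattens a [compute_pixel_metrics()] result to one row per pixel with
#' coordinates, all metric fields, the validity flag and exclusion reason
#' -- the input expected by [bin_by_map()] and friends.
#'
#' @param x A `pixel_metrics` object.
#' @param row.names,optional Ignored (S3 signature).
#' @param valid_only Keep only valid pixels.
#' @param ... Unused.
#' @export
as.data.frame.pixel_metrics <- function(x, row.names = NULL, optional = FALSE,
                                        valid_only = FALSE, ...) {
  g <- x$grid
  df <- data.frame(row = rep(seq_len(g$nrow), times = g$ncol),
                   col = rep(seq_len(g$ncol), each = g$nrow),
                   lon = rep(grid_lon(g), each = g$nrow),
                   lat = rep(grid_lat(g), times = g$ncol))
  for (nm in c("map_mm", "p_normal", "p_dry", "ndvi_normal", "ndvi_dry",
               "ndvi_post", "rain_reduction", "ndvi_reduction", "resistance",
               "resilience_normal", "resilience_dry", "resilience"))
    df[[nm]] <- as.vector(x[[nm]])
  df$valid <- as.vector(x$valid)
  df$exclusion_reason <- as.vector(x$exclusion_reason)
  if (valid_only) df <- df[df$valid, , drop = FALSE]
  df
}

#' Write per-pixel metrics to disk
#'
#' Writes the per-pixel CSV plus one ASCII grid per metric band
#' (`map_mm`, `rain_reduction`, `ndvi_reduction`, `resistance`,
#' `resilience`, `valid`, `exclusion_code`).
#'
#' @param metrics A `pixel_metrics` object.
#' @param dir Output directory.
#' @export
write_pixel_metrics <- function(metrics, dir) {
  stopifnot(inherits(metrics, "pixel_metrics"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(metrics)
  write.csv(df, file.path(dir, "pixel_metrics.csv"), row.names = FALSE)
  for (nm in c("map_mm", "rain_reduction", "ndvi_reduction", "resistance",
               "resilience"))
    write_asc(metrics[[nm]], metrics$grid,
              file.path(dir, paste0(nm, ".asc")))
  write_asc(metrics$valid + 0, metrics$grid, file.path(dir, "valid.asc"))
  code <- matrix(match(metrics$exclusion_reason,
                       c("none", "nodata", "no_rain_reduction",
                         "ndvi_reduction_below_min")) - 1L,
                 nrow(metrics$valid), ncol(metrics$valid))
  write_asc(code, metrics$grid, file.path(dir, "exclusion_code.asc"))
  invisible(dir)
}
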