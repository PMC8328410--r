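#' Regional annual anomaly series
#'
#' Per year, the spatial mean of the cube over valid (non-missing) pixels,
#' minus the mean of those yearly means over the whole series. By
#' construction the anomalies sum to zero over the series; the subtracted
#' whole-series mean is kept as the `baseline` attribute.
#'
#' @param cube A [grid_cube()].
#' @param weights `"uniform"` (default) or `"coslat"` (cosine-latitude
#'   area weighting).
#' @return A `data.frame` of class `anomaly_series` with columns `year`,
#'   `mean` (yearly spatial mean) and `anomaly`; attribute `baseline` is
#'   the whole-series mean.
#' @export
regional_anomaly <- function(cube, weights = c("uniform", "coslat")) {
  weights <- match.arg(weights)
  stopifnot(inherits(cube, "grid_cube"), length(cube$years) >= 2L)
  w <- if (weights == "coslat") {
    matrix(cos(grid_lat(cube$grid) * pi / 180), cube$grid$nrow,
           cube$grid$ncol)
  } else matrix(1, cube$grid$nrow, cube$grid$ncol)
  yearly <- vapply(seq_along(cube$years), function(k) {
    sl <- cube$values[, , k]
    ok <- !is.na(sl)
    if (!any(ok)) stop_("no valid pixels in year %d", cube$years[k])
    sum(w[ok] * sl[ok]) / sum(w[ok])
  }, numeric(1))
  baseline <- mean(yearly)
  out <- data.frame(year = cube$years, mean = yearly,
                    anomaly = yearly - baseline)
  attr(out, "baseline") <- baseline
  attr(out, "weights") <- weights
  class(out) <- c("anomaly_series", "data.frame")
  out
}

#' Build an anomaly series from yearly values directly
#'
#' @param years Gapless increasing calendar years.
#' @param yearly Regional yearly means.
#' @export
anomaly_series <- function(years, yearly) {
  years <- check_years_gapless(as.integer(years))
  stopifnot(length(years) == length(yearly))
  baseline <- mean(yearly)
  out <- data.frame(year = years, mean = yearly, anomaly = yearly - baseline)
  attr(out, "baseline") <- baseline
  class(out) <- c("anomaly_series", "data.frame")
  out
}

#' Partition the year axis into normal / dry / recovery periods
#'
#' In `explicit` mode the three supplied inclusive year ranges are
#' validated (disjoint, contiguous, jointly covering the series, in
#' normal < dry < recovery order) and returned. In `auto` mode the dry
#' period is detected from the anomaly series as the longest maximal run
#' of at least `min_run` consecutive below-baseline years that does not
#' start at the series start (a dry run with no preceding normal baseline
#' is an error); length ties are broken toward the run with the more
#' negative mean anomaly. All years before the run form the normal period
#' and all years after it the recovery period (which may be empty if the
#' run reaches the series end).
#'
#' @param anom An [anomaly_series()].
#' @param mode `"explicit"` or `"auto"`.
#' @param normal,dry,recovery Year vectors (explicit mode); any contiguous
#'   integer vector, e.g. `1982:1998`.
#' @param min_run Minimum dry-run length in auto mode (default 5).
#' @return An object of class `period_partition` with fields
#'   `normal_years`, `dry_years`, `recovery_years`.
#' @export
partition_years <- function(anom, mode = c("explicit", "auto"),
                            normal = NULL, dry = NULL, recovery = NULL,
                            min_run = 5L) {
  mode <- match.arg(mode)
  stopifnot(inherits(anom, "anomaly_series"))
  years <- anom$year
  if (mode == "explicit") {
    normal <- as.integer(normal); dry <- as.integer(dry)
    recovery <- as.integer(recovery)
    all3 <- c(normal, dry, recovery)
    if (anyDuplicated(all3)) stop_("period year ranges overlap")
    if (!setequal(all3, years))
      stop_("period ranges must jointly cover the series years %d-%d",
            min(years), max(years))
    if (length(normal) && length(dry) && max(normal) >= min(dry))
      stop_("normal period must precede the dry period")
    if (length(recovery) && max(dry) >= min(recovery))
      stop_("dry period must precede the recovery period")
    for (p in list(normal, dry, recovery))
      if (length(p) && !all(diff(sort(p)) == 1L))
        stop_("period year ranges must be contiguous")
    if (!length(dry)) stop_("dry period is empty")
    if (!length(normal)) stop_("normal period is empty")
    part <- list(normal_years = sort(normal), dry_years = sort(dry),
                 recovery_years = sort(recovery))
  } else {
    if (length(years) < min_run + 2L)
      stop_("series too short for auto mode (need >= min_run + 2 years)")
    neg <- anom$anomaly < 0
    r <- rle(neg)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values & r$lengths >= min_run)
    cand <- cand[starts[cand] > 1L]  # must leave a normal baseline
    if (!length(cand)) {
      if (any(r$values & r$lengths >= min_run))
        stop_("dry period starts at the series start: no normal baseline")
      stop_("no dry period detected")
    }
    len <- r$lengths[cand]
    best <- cand[len == max(len)]
    if (length(best) > 1L) {
      run_mean <- vapply(best, function(j)
        mean(anom$anomaly[starts[j]:ends[j]]), numeric(1))
      best <- best[which.min(run_mean)]
    } else best <- best[1]
    i0 <- starts[best]; i1 <- ends[best]
    part <- list(normal_years = years[seq_len(i0 - 1L)],
                 dry_years = years[i0:i1],
                 recovery_years = if (i1 < length(years))
                   years[(i1 + 1L):length(years)] else integer(0))
  }
  structure(c(part, list(mode = mode)), class = "period_partition")
}

#' @export
print.period_partition <- function(x, ...) {
  fmt <- function(y) if (!length(y)) "(empty)" else
    sprintf("%d-%d (%d yr)", min(y), max(y), length(y))
  cat("<period_partition>\n")
  cat("  normal:  ", fmt(x$normal_years), "\n")
  cat("  dry:     ", fmt(x$dry_years), "\n")
  cat("  recovery:", fmt(x$recovery_years), "\n")
  invisible(x)
}

#' Regional and per-pixel period statistics
#'
#' Computes, regionally and per pixel, the mean over the normal, dry, and
#' recovery years, plus the dry-period deficit as a percentage of the
#' all-years mean (positive = below average) and the normal-period excess
#' on the same convention.
#'
#' @param cube A [grid_cube()].
#' @param part A [partition_years()] result.
#' @param weights Spatial weighting for the regional means (see
#'   [regional_anomaly()]).
#' @return A list of class `period_stats`: `regional` (named means,
#'   `deficit_pct`, `excess_pct`) and `pixel` (list of matrices
#'   `normal`, `dry`, `recovery`, `all`).
#' @export
period_stats <- function(cube, part, weights = c("uniform", "coslat")) {
  weights <- match.arg(weights)
  stopifnot(inherits(cube, "grid_cube"), inherits(part, "period_partition"))
  for (nm in c("normal_years", "dry_years")) {
    if (!length(part[[nm]])) stop_("%s is empty", nm)
  }
  miss <- setdiff(c(part$normal_years, part$dry_years, part$recovery_years),
                  cube$years)
  if (length(miss)) stop_("partition year %d not in cube", miss[1])
  anom <- regional_anomaly(cube, weights = weights)
  reg_mean <- function(yrs) if (!length(yrs)) NA_real_ else
    mean(anom$mean[anom$year %in% yrs])
  all_mean <- attr(anom, "baseline")
  reg <- list(normal = reg_mean(part$normal_years),
              dry = reg_mean(part$dry_years),
              recovery = reg_mean(part$recovery_years),
              all = all_mean,
              deficit_pct = 100 * (all_mean - reg_mean(part$dry_years)) /
                all_mean,
              excess_pct = 100 * (reg_mean(part$normal_years) - all_mean) /
                all_mean)
  pix <- list(normal = period_mean(cube, part$normal_years),
              dry = period_mean(cube, part$dry_years),
              recovery = if (length(part$recovery_years))
                period_mean(cube, part$recovery_years) else NULL,
              all = period_mean(cube, cube$years))
  structure(list(regional = reg, pixel = pix, partition = part),
            class = "period_stats")
}

#' @export
print.period_stats <- function(x, ...) {
  r <- x$regional
  cat("<period_stats> regional means:\n")
  cat(sprintf("  normal %.4g, dry %.4g, recovery %.4g, all %.4g\n",
              r$normal, r$dry, r$recovery, r$all))
  cat(sprintf("  dry-period deficit %.2f%% of the all-years mean\n",
              r$deficit_pct))
  invisible(x)
}

## Per-pixel mean over a set of years; all-missing pixels stay NA.
period_mean <- function(cube, years) {
  k <- match(years, cube$years)
  if (anyNA(k)) stop_("year %d not in cube", years[is.na(k)][1])
  slab <- cube$values[, , k, drop = FALSE]
  n_ok <- rowSums(!is.na(slab), dims = 2)
  s <- rowSums(slab, dims = 2, na.rm = TRUE)
  out <- s / n_ok
  out[n_ok == 0L] <- NA_real_
  out
}
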