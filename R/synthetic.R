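#' Ground-truth configuration for synthetic scenes
#'
#' Defines the statistical structure a synthetic scene emulates: a
#' 32-year annual series (17 normal + 13 dry + 2 recovery years), a
#' west-to-east mean-annual-precipitation (MAP) gradient spanning
#' 40-500 mm, a regional dry-period deficit of 11.5% of the whole-series
#' mean with a normal-period excess of 4.9% (the recovery-year multiplier
#' is derived so the whole-series mean equals the true MAP), a dry-period
#' rain reduction that increases with MAP, and imposed resistance and
#' resilience functions of MAP with known form.
#'
#' Noise model: station and gridded precipitation carry i.i.d.
#' multiplicative noise per value (`noise_sd_precip`) plus a shared
#' regional year-to-year multiplier (`interannual_sd`); NDVI noise is
#' multiplicative per 15-day composite (`noise_sd_ndvi`,
#' `composites_per_year` of them averaged into each annual value, as in
#' composite satellite products). Setting `composites_per_year = 1`
#' applies the noise directly per year.
#'
#' @param n_years_normal,n_years_dry,n_years_recovery Period lengths
#'   (defaults 17, 13, 2).
#' @param start_year First calendar year (default 1982).
#' @param map_range True MAP range in mm across the grid (default
#'   `c(40, 500)`).
#' @param dry_deficit Regional dry-period deficit as a fraction of the
#'   whole-series mean (default 0.115).
#' @param normal_excess Regional normal-period excess over the
#'   whole-series mean (default 0.049).
#' @param deficit_map_slope Relative spread of the per-pixel rain
#'   reduction around its regional mean along the MAP axis (default 1.35:
#'   the reduction rises from a few percent at the xeric end to >20% at
#'   the mesic end while preserving the regional deficit).
#' @param deficit_spatial_sd Relative sd of the seeded smooth spatial
#'   multiplier on the rain-reduction field (default 0.3). This is the
#'   MAP-independent heterogeneity of the drought pattern; it is what
#'   makes a subset of pixels with similar rain reduction span a wide MAP
#'   range, as in real deficit maps. Set to 0 for a reduction that is a
#'   pure function of MAP.
#' @param resistance_fn True resistance as a function of MAP (mm);
#'   default: affine, 1 at the dry end of `map_range` to 6 at the wet
#'   end.
#' @param resilience_fn True resilience as a function of MAP; default:
#'   quadratic with its maximum 1.1 at 250 mm, falling to 0.7 at the far
#'   end of the range.
#' @param ndvi_max,ndvi_half_sat Saturating normal-state NDVI curve
#'   `ndvi_max * MAP / (ndvi_half_sat + MAP)` (defaults 0.8 and 200 mm).
#' @param noise_sd_precip Relative precipitation noise sd per
#'   station-year / pixel-year (default 0.05).
#' @param noise_sd_ndvi Relative NDVI noise sd per composite (default
#'   0.05).
#' @param composites_per_year NDVI composites averaged per year
#'   (default 24).
#' @param interannual_sd Sd of the shared regional year multiplier
#'   (default 0.02; small, so every normal year stays above and every dry
#'   year below the long-term mean, as in the emulated study period).
#' @param map_noise_sd Amplitude (mm) of the smooth spatial noise added
#'   to the MAP gradient (default 20).
#' @param n_stations Number of synthetic stations (default 51).
#' @param seed Integer seed fixing all randomness (default 1).
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(n_years_normal = 17L, n_years_dry = 13L,
                         n_years_recovery = 2L, start_year = 1982L,
                         map_range = c(40, 500), dry_deficit = 0.115,
                         normal_excess = 0.049, deficit_map_slope = 1.35,
                         deficit_spatial_sd = 0.3,
                         resistance_fn = NULL, resilience_fn = NULL,
                         ndvi_max = 0.8, ndvi_half_sat = 200,
                         noise_sd_precip = 0.05, noise_sd_ndvi = 0.05,
                         composites_per_year = 24L, interannual_sd = 0.02,
                         map_noise_sd = 20, n_stations = 51L, seed = 1L) {
  stopifnot(n_years_normal >= 1, n_years_dry >= 1, n_years_recovery >= 1,
            length(map_range) == 2, map_range[1] > 0,
            map_range[2] > map_range[1],
            dry_deficit > 0, dry_deficit < 1,
            normal_excess >= 0, normal_excess < 1,
            noise_sd_precip >= 0, noise_sd_ndvi >= 0, interannual_sd >= 0,
            deficit_spatial_sd >= 0,
            composites_per_year >= 1, n_stations >= 4)
  lo <- map_range[1]; hi <- map_range[2]
  if (is.null(resistance_fn))
    resistance_fn <- function(map) 1 + 5 * (map - lo) / (hi - lo)
  if (is.null(resilience_fn)) {
    far <- max(abs(c(lo, hi) - 250))
    kk <- 0.4 / far^2
    resilience_fn <- function(map) 1.1 - kk * (map - 250)^2
  }
  cfg <- list(n_years_normal = as.integer(n_years_normal),
              n_years_dry = as.integer(n_years_dry),
              n_years_recovery = as.integer(n_years_recovery),
              start_year = as.integer(start_year),
              map_range = map_range, dry_deficit = dry_deficit,
              normal_excess = normal_excess,
              deficit_map_slope = deficit_map_slope,
              deficit_spatial_sd = deficit_spatial_sd,
              resistance_fn = resistance_fn, resilience_fn = resilience_fn,
              ndvi_max = ndvi_max, ndvi_half_sat = ndvi_half_sat,
              noise_sd_precip = noise_sd_precip,
              noise_sd_ndvi = noise_sd_ndvi,
              composites_per_year = as.integer(composites_per_year),
              interannual_sd = interannual_sd, map_noise_sd = map_noise_sd,
              n_stations = as.integer(n_stations), seed = as.integer(seed))
  ## regional mean rain reduction relative to the normal period implied by
  ## the two anomaly fractions: 1 - (1 - dry_deficit) / (1 + normal_excess)
  cfg$rr_mean <- 1 - (1 - dry_deficit) / (1 + normal_excess)
  if (cfg$rr_mean * (1 + deficit_map_slope / 2) >= 1)
    stop_("deficit_map_slope too large: rain reduction reaches 1")
  test_res <- resistance_fn(seq(lo, hi, length.out = 11))
  if (any(test_res <= 0)) stop_("resistance_fn must be positive on map_range")
  structure(cfg, class = "truth_config")
}

#' @export
print.truth_config <- function(x, ...) {
  cat(sprintf("<truth_config> %d+%d+%d years from %d, MAP %g-%g mm, seed %d\n",
              x$n_years_normal, x$n_years_dry, x$n_years_recovery,
              x$start_year, x$map_range[1], x$map_range[2], x$seed))
  cat(sprintf("  dry deficit %.1f%%, normal excess %.1f%% (whole-mean scale); noise: precip %.3g, ndvi %.3g/composite, interannual %.3g\n",
              100 * x$dry_deficit, 100 * x$normal_excess,
              x$noise_sd_precip, x$noise_sd_ndvi, x$interannual_sd))
  invisible(x)
}

## Year axis and period structure implied by a config
truth_years <- function(config) {
  n <- config$n_years_normal + config$n_years_dry + config$n_years_recovery
  seq(config$start_year, length.out = n)
}

truth_partition <- function(config) {
  y <- truth_years(config)
  i1 <- config$n_years_normal
  i2 <- i1 + config$n_years_dry
  structure(list(normal_years = y[seq_len(i1)],
                 dry_years = y[(i1 + 1):i2],
                 recovery_years = y[(i2 + 1):length(y)],
                 mode = "truth"),
            class = "period_partition")
}

## Normalized MAP position in [0, 1]
map_u <- function(map, config)
  pmin(pmax((map - config$map_range[1]) /
              (config$map_range[2] - config$map_range[1]), 0), 1)

## True per-pixel rain reduction (vs the normal period) as a function of MAP.
## The profile is centered at the MAP-weighted mean position `u_center` so
## that the *regional* precipitation series (whose spatial mean weights
## pixels by their MAP) realizes the configured dry-period deficit; pass
## the u_center of the full scene surface when evaluating at a subset of
## sites.
true_rain_reduction <- function(map, config, u_center = NULL) {
  uc <- u_center %||% map_u_center(map, config)
  config$rr_mean * (1 + config$deficit_map_slope * (map_u(map, config) - uc))
}

## MAP-weighted mean of the normalized gradient position
map_u_center <- function(map_true, config)
  sum(map_true * map_u(map_true, config)) / sum(map_true)

## Per-pixel true rain-reduction field: the MAP profile modulated by a
## seeded smooth spatial multiplier (deficit_spatial_sd), so that similar
## reductions occur across a range of MAP values, as in real drought
## patterns. Pixels where the perturbed reduction is <= 0 are genuinely
## unreduced and end up excluded by the validity filter downstream.
rain_reduction_field <- function(map_true, config) {
  rr <- true_rain_reduction(map_true, config)
  if (config$deficit_spatial_sd > 0) {
    delta <- with_seed(config$seed + 606L,
                       upsample_bilinear(matrix(rnorm(36), 6, 6),
                                         nrow(map_true), ncol(map_true)))
    rr <- rr * (1 + config$deficit_spatial_sd * delta)
  }
  rr
}

## Per-period year multipliers relative to the whole-series (= true MAP)
## mean; the recovery multiplier is derived so the multipliers average to 1.
year_multipliers <- function(config, rr_pixel) {
  nn <- config$n_years_normal; nd <- config$n_years_dry
  nr <- config$n_years_recovery
  m_norm <- 1 + config$normal_excess
  m_dry <- m_norm * (1 - rr_pixel)          # per pixel
  m_dry_mean <- m_norm * (1 - config$rr_mean)
  m_rec <- ((nn + nd + nr) - nn * m_norm - nd * m_dry_mean) / nr
  list(normal = m_norm, dry = m_dry, recovery = m_rec)
}

#' Generate the true mean-annual-precipitation surface
#'
#' A smooth, strictly monotone west-to-east gradient spanning
#' `map_range`, plus seeded smooth spatial noise (a coarse random field
#' bilinearly upsampled), clipped back to `map_range`.
#'
#' @param config A [truth_config()].
#' @param grid A [grid_spec()].
#' @return Matrix of true MAP (mm) on the grid.
#' @export
generate_map_surface <- function(config, grid) {
  stopifnot(inherits(config, "truth_config"), inherits(grid, "grid_spec"))
  lo <- config$map_range[1]; hi <- config$map_range[2]
  colfrac <- (seq_len(grid$ncol) - 0.5) / grid$ncol
  base <- matrix(rep(lo + (hi - lo) * colfrac, each = grid$nrow),
                 grid$nrow, grid$ncol)
  if (config$map_noise_sd > 0) {
    noise <- with_seed(config$seed + 101L, {
      coarse <- matrix(rnorm(6 * 6), 6, 6)
      upsample_bilinear(coarse, grid$nrow, grid$ncol)
    }) * config$map_noise_sd
    base <- base + noise
  }
  pmin(pmax(base, lo), hi)
}

## Bilinear upsampling of a small matrix onto nr x nc (used for smooth
## spatial noise fields)
upsample_bilinear <- function(m, nr, nc) {
  sr <- nrow(m); sc <- ncol(m)
  pr <- seq(1, sr, length.out = nr)
  pc <- seq(1, sc, length.out = nc)
  r0 <- pmin(floor(pr), sr - 1L); fr <- pr - r0
  c0 <- pmin(floor(pc), sc - 1L); fc <- pc - c0
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    cj <- c0[j]; fj <- fc[j]
    out[, j] <- (1 - fr) * ((1 - fj) * m[r0, cj] + fj * m[r0, cj + 1L]) +
      fr * ((1 - fj) * m[r0 + 1L, cj] + fj * m[r0 + 1L, cj + 1L])
  }
  out
}

#' Generate synthetic station annual-precipitation records
#'
#' Places `n_stations` stations at seeded random distinct grid cells and
#' generates, per station-year, `MAP_true(site) * multiplier(year, site) *
#' (1 + noise)`: the multiplier is the normal-period excess in normal
#' years, the MAP-dependent dry-period reduction in dry years, and the
#' derived wet recovery multiplier afterwards, all modulated by the
#' shared interannual term. Values are clamped at 0.
#'
#' @param map_true True MAP matrix from [generate_map_surface()].
#' @param config A [truth_config()].
#' @param grid The [grid_spec()] of `map_true`.
#' @return A [station_table()].
#' @export
generate_station_records <- function(map_true, config, grid) {
  stopifnot(inherits(config, "truth_config"))
  if (config$n_stations > length(map_true))
    stop_("n_stations (%d) exceeds the number of grid cells (%d)",
          config$n_stations, length(map_true))
  years <- truth_years(config)
  eta <- interannual_multipliers(config)
  with_seed(config$seed + 202L, {
    cells <- sample(length(map_true), config$n_stations)
    ri <- (cells - 1L) %% nrow(map_true) + 1L
    ci <- (cells - 1L) %/% nrow(map_true) + 1L
    lon <- grid_lon(grid)[ci]; lat <- grid_lat(grid)[ri]
    msite <- map_true[cbind(ri, ci)]
    rr <- rain_reduction_field(map_true, config)[cbind(ri, ci)]
    mult <- sapply(seq_along(years), function(k)
      period_multiplier(k, config, rr))            # n_stations x n_years
    noise <- matrix(rnorm(length(msite) * length(years), 0,
                          config$noise_sd_precip),
                    length(msite), length(years))
    val <- msite * mult * sweep(1 + noise, 2L, eta, `*`)
    df <- data.frame(
      station_id = rep(sprintf("S%03d", seq_along(msite)),
                       times = length(years)),
      lon = rep(lon, times = length(years)),
      lat = rep(lat, times = length(years)),
      year = rep(years, each = length(msite)),
      precip_mm = pmax(as.vector(val), 0))
    station_table(df)
  })
}

## multiplier of year index k for pixels/sites with true rain reduction rr
period_multiplier <- function(k, config, rr) {
  m <- year_multipliers(config, rr)
  if (k <= config$n_years_normal) rep(m$normal, length(rr))
  else if (k <= config$n_years_normal + config$n_years_dry) m$dry
  else rep(m$recovery, length(rr))
}

## shared regional year multipliers (1 + eta_t)
interannual_multipliers <- function(config) {
  n <- length(truth_years(config))
  if (config$interannual_sd == 0) return(rep(1, n))
  with_seed(config$seed + 303L, 1 + rnorm(n, 0, config$interannual_sd))
}

#' Generate the gridded precipitation cube
#'
#' Same generative model as the station records, applied at every pixel
#' with independent pixel-year noise.
#'
#' @inheritParams generate_station_records
#' @return A precipitation [grid_cube()].
#' @export
generate_precip_cube <- function(map_true, config, grid) {
  years <- truth_years(config)
  rr <- rain_reduction_field(map_true, config)
  eta <- interannual_multipliers(config)
  vals <- array(NA_real_, c(grid$nrow, grid$ncol, length(years)))
  noise <- if (config$noise_sd_precip > 0)
    with_seed(config$seed + 404L,
              array(rnorm(length(map_true) * length(years), 0,
                          config$noise_sd_precip),
                    c(grid$nrow, grid$ncol, length(years))))
  else array(0, c(grid$nrow, grid$ncol, length(years)))
  for (k in seq_along(years)) {
    mult <- matrix(period_multiplier(k, config, rr), grid$nrow, grid$ncol)
    vals[, , k] <- pmax(map_true * mult * eta[k] * (1 + noise[, , k]), 0)
  }
  grid_cube(vals, years, grid, type = "precip")
}

#' Generate the NDVI cube consistent with the imposed truth
#'
#' Inverts the response metrics so the pipeline's estimators have known
#' truth: the normal-state NDVI is a saturating function of MAP; each
#' dry-year NDVI is depressed by `rain_reduction_true / resistance_true`;
#' each recovery-year NDVI is `resilience_true` times the normal state
#' (the normal-denominator resilience convention; set
#' `resilience_mode = "dry"` to generate under the dry-denominator
#' convention instead). Annual values are means of
#' `composites_per_year` noisy composites. Values implying NDVI outside
#' `[0, 1]` are clipped; the clip count is reported via a warning.
#'
#' @inheritParams generate_station_records
#' @param resilience_mode Which resilience convention the recovery years
#'   encode: `"normal"` (default) or `"dry"`.
#' @return An NDVI [grid_cube()].
#' @export
generate_ndvi_cube <- function(map_true, config, grid,
                               resilience_mode = c("normal", "dry")) {
  resilience_mode <- match.arg(resilience_mode)
  years <- truth_years(config)
  rr <- rain_reduction_field(map_true, config)
  res_true <- config$resistance_fn(map_true)
  if (any(res_true <= 0)) stop_("resistance_fn must be positive")
  resil_true <- config$resilience_fn(map_true)
  n_normal <- config$ndvi_max * map_true / (config$ndvi_half_sat + map_true)
  n_dry <- n_normal * (1 - rr / res_true)
  n_post <- if (resilience_mode == "normal") resil_true * n_normal
            else resil_true * n_dry
  vals <- array(NA_real_, c(grid$nrow, grid$ncol, length(years)))
  ncomp <- config$composites_per_year
  annual_noise <- if (config$noise_sd_ndvi > 0) {
    with_seed(config$seed + 505L, {
      ## mean of ncomp iid multiplicative composite-noise terms
      matrix(rnorm(length(map_true) * length(years) * 1L, 0,
                   config$noise_sd_ndvi / sqrt(ncomp)),
             length(map_true), length(years))
    })
  } else matrix(0, length(map_true), length(years))
  n_clip <- 0L
  for (k in seq_along(years)) {
    base <- if (k <= config$n_years_normal) n_normal
            else if (k <= config$n_years_normal + config$n_years_dry) n_dry
            else n_post
    v <- base * (1 + matrix(annual_noise[, k], grid$nrow, grid$ncol))
    n_clip <- n_clip + sum(v < 0 | v > 1)
    vals[, , k] <- pmin(pmax(v, 0), 1)
  }
  if (n_clip > 0L)
    warning(sprintf("%d NDVI values clipped to [0, 1]", n_clip),
            call. = FALSE)
  grid_cube(vals, years, grid, type = "ndvi")
}

#' Generate a complete synthetic scene
#'
#' Composes the MAP surface, station records, precipitation cube, NDVI
#' cube, and the true period partition into one reproducible scene.
#'
#' @param config A [truth_config()].
#' @param grid A [grid_spec()]; default a 100 x 100 grid at 0.083 deg
#'   over a steppe-like lon/lat window.
#' @param resilience_mode Passed to [generate_ndvi_cube()].
#' @return An object of class `synthetic_scene`: `truth` (matrices
#'   `map`, `rain_reduction`, `resistance`, `resilience`), `stations`,
#'   `precip_cube`, `ndvi_cube`, `partition_true`, `config`, `grid`.
#' @export
generate_scene <- function(config = truth_config(),
                           grid = grid_spec(100, 100, xmin = 105,
                                            ymax = 46, cellsize = 0.083),
                           resilience_mode = c("normal", "dry")) {
  resilience_mode <- match.arg(resilience_mode)
  map_true <- generate_map_surface(config, grid)
  scene <- list(
    truth = list(map = map_true,
                 rain_reduction = rain_reduction_field(map_true, config),
                 resistance = config$resistance_fn(map_true),
                 resilience = config$resilience_fn(map_true)),
    stations = generate_station_records(map_true, config, grid),
    precip_cube = generate_precip_cube(map_true, config, grid),
    ndvi_cube = generate_ndvi_cube(map_true, config, grid,
                                   resilience_mode = resilience_mode),
    partition_true = truth_partition(config),
    config = config, grid = grid)
  class(scene) <- "synthetic_scene"
  scene
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d pixels, %d years, %d stations, seed %d\n",
              x$grid$nrow, x$grid$ncol, length(x$precip_cube$years),
              x$config$n_stations, x$config$seed))
  print(x$partition_true)
  invisible(x)
}

#' Write a synthetic scene to an output directory
#'
#' Writes the station CSV, both cubes as yearly ASCII-grid stacks, the
#' truth rasters, and a JSON truth manifest.
#'
#' @param scene A [generate_scene()] result.
#' @param dir Output directory.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(scene$stations),
            file.path(dir, "stations.csv"), row.names = FALSE)
  write_cube(scene$precip_cube, file.path(dir, "precip"), prefix = "precip")
  write_cube(scene$ndvi_cube, file.path(dir, "ndvi"), prefix = "ndvi")
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in names(scene$truth))
    write_asc(scene$truth[[nm]], scene$grid,
              file.path(tdir, paste0(nm, ".asc")))
  part <- scene$partition_true
  manifest <- list(
    seed = scene$config$seed,
    years = range(truth_years(scene$config)),
    partition = list(normal = range(part$normal_years),
                     dry = range(part$dry_years),
                     recovery = range(part$recovery_years)),
    map_range = scene$config$map_range,
    dry_deficit = scene$config$dry_deficit,
    normal_excess = scene$config$normal_excess,
    noise_sd_precip = scene$config$noise_sd_precip,
    noise_sd_ndvi = scene$config$noise_sd_ndvi)
  jsonlite::write_json(manifest, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
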