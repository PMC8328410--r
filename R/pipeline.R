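#' Default pipeline configuration
#'
#' Returns the full configuration list with every analysis parameter at
#' its documented default; `read_pipeline_config()` merges a YAML file
#' over these defaults.
#'
#' @return Named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    paths = list(ndvi = NULL, stations = NULL, mask = NULL,
                 output = "ecostab-out"),
    period = list(mode = "explicit",
                  normal = c(1982L, 1998L), dry = c(1999L, 2011L),
                  recovery = c(2012L, 2013L), min_run = 5L),
    min_ndvi_reduction = 0.01,
    resilience_denominator = "normal",
    map_window = "all",
    bin_width = 50,
    n_min = 10L,
    subset_rain_reduction = c(0.05, 0.10),
    smoothing = "gcv",
    weights = "uniform",
    seed = 1L),
    class = "pipeline_config")
}

#' Read a YAML pipeline configuration
#'
#' Keys present in the file override [default_pipeline_config()]; nested
#' keys (`paths`, `period`) merge element-wise.
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- unclass(default_pipeline_config())
  for (k in names(usr)) {
    if (k %in% c("paths", "period") && is.list(usr[[k]])) {
      for (j in names(usr[[k]])) cfg[[k]][[j]] <- usr[[k]][[j]]
    } else cfg[[k]] <- usr[[k]]
  }
  validate_pipeline_config(structure(cfg, class = "pipeline_config"))
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$min_ndvi_reduction >= 0, cfg$min_ndvi_reduction < 1,
            cfg$bin_width > 0, cfg$n_min >= 0,
            length(cfg$subset_rain_reduction) == 2,
            cfg$subset_rain_reduction[1] < cfg$subset_rain_reduction[2],
            cfg$resilience_denominator %in% c("normal", "dry"),
            cfg$map_window %in% c("all", "normal"),
            cfg$period$mode %in% c("explicit", "auto"))
  if (!identical(cfg$smoothing, "gcv"))
    stopifnot(is_scalar_number(cfg$smoothing), cfg$smoothing >= 0)
  cfg
}

expand_range <- function(r) {
  if (length(r) == 2L) seq(as.integer(r[1]), as.integer(r[2]))
  else as.integer(r)
}

#' Run the full analysis pipeline
#'
#' Executes interpolation, period partition, per-pixel metrics, and the
#' gradient analyses (all-pixel and rain-reduction-subset variants) on
#' the configured inputs, writing every artifact under the configured
#' output directory. Stage-by-stage pixel counts and the exclusion tally
#' are logged via `message()`; identical config and inputs produce
#' byte-identical CSV/JSON outputs.
#'
#' @param config A `pipeline_config` (list), a YAML path, or `NULL` for
#'   defaults.
#' @param ndvi,stations,mask Optional pre-loaded inputs (a [grid_cube()],
#'   [station_table()], and logical mask) that override the configured
#'   paths -- convenient when driving the pipeline from a generated
#'   scene in memory.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list with the computed objects (`precip`,
#'   `anomaly`, `partition`, `stats`, `metrics`, `profiles`, `fits`) and
#'   the output directory.
#' @export
run_pipeline <- function(config = NULL, ndvi = NULL, stations = NULL,
                         mask = NULL, quiet = FALSE) {
  cfg <- if (is.null(config)) default_pipeline_config()
         else if (is.character(config)) read_pipeline_config(config)
         else validate_pipeline_config(
           structure(utils::modifyList(unclass(default_pipeline_config()),
                                       unclass(config)),
                     class = "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- cfg$paths$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## --- inputs -------------------------------------------------------
  if (is.null(ndvi)) {
    if (is.null(cfg$paths$ndvi)) stop_("stage input: no NDVI cube provided")
    ndvi <- read_cube(cfg$paths$ndvi, type = "ndvi")
  }
  if (is.null(stations)) {
    if (is.null(cfg$paths$stations))
      stop_("stage input: no station table provided")
    stations <- read_stations(cfg$paths$stations)
  }
  if (is.null(mask) && !is.null(cfg$paths$mask))
    mask <- read_mask(cfg$paths$mask)
  say("input: NDVI %d x %d x %d years; %d station records",
      dim(ndvi)[1], dim(ndvi)[2], dim(ndvi)[3], nrow(stations))

  ## --- interpolate --------------------------------------------------
  precip <- tryCatch(
    interpolate_precip(stations, ndvi$grid, smoothing = cfg$smoothing,
                       years = intersect(stations$year, ndvi$years)),
    error = function(e) stop_("stage interpolate: %s", conditionMessage(e)))
  say("interpolate: %d yearly thin-plate surfaces on the NDVI grid",
      length(precip$years))
  if (!is.null(mask)) {
    ndvi <- apply_mask(ndvi, mask)
    precip <- apply_mask(precip, mask)
    say("mask: %d of %d pixels retained", sum(mask), length(mask))
  }

  ## --- periods ------------------------------------------------------
  anom <- tryCatch(regional_anomaly(precip, weights = cfg$weights),
                   error = function(e)
                     stop_("stage periods: %s", conditionMessage(e)))
  part <- tryCatch({
    if (cfg$period$mode == "explicit")
      partition_years(anom, "explicit",
                      normal = expand_range(cfg$period$normal),
                      dry = expand_range(cfg$period$dry),
                      recovery = expand_range(cfg$period$recovery))
    else partition_years(anom, "auto", min_run = cfg$period$min_run)
  }, error = function(e) stop_("stage periods: %s", conditionMessage(e)))
  stats <- period_stats(precip, part, weights = cfg$weights)
  say("periods: normal %d-%d, dry %d-%d, recovery %d-%d; dry deficit %.1f%%",
      min(part$normal_years), max(part$normal_years),
      min(part$dry_years), max(part$dry_years),
      min(part$recovery_years), max(part$recovery_years),
      stats$regional$deficit_pct)
  write.csv(data.frame(year = anom$year, anomaly = anom$anomaly),
            file.path(out_dir, "anomaly_precip.csv"), row.names = FALSE)

  ## --- metrics ------------------------------------------------------
  metrics <- tryCatch(
    compute_pixel_metrics(precip, ndvi, part,
                          min_ndvi_reduction = cfg$min_ndvi_reduction,
                          resilience_denominator = cfg$resilience_denominator,
                          map_window = cfg$map_window),
    error = function(e) stop_("stage metrics: %s", conditionMessage(e)))
  tally <- exclusion_counts(metrics)
  say("metrics: %d valid pixels; exclusions: %s", sum(metrics$valid),
      paste(sprintf("%s=%d", names(tally)[-1], tally[-1]), collapse = ", "))
  if (sum(metrics$valid) == 0L)
    stop_("stage metrics: no valid pixels after filtering")
  if (mean(metrics$valid) < 0.05)
    warning("fewer than 5% of pixels valid after filtering", call. = FALSE)
  write_pixel_metrics(metrics, file.path(out_dir, "metrics"))

  ## --- gradient -----------------------------------------------------
  px <- as.data.frame(metrics)
  gdir <- file.path(out_dir, "gradient")
  dir.create(gdir, showWarnings = FALSE, recursive = TRUE)
  profiles <- list(); fitsets <- list()
  run_gradient <- function(tab, response, tag) {
    pr <- tryCatch(bin_by_map(tab, response, width = cfg$bin_width,
                              n_min = cfg$n_min),
                   error = function(e)
                     stop_("stage gradient (%s): %s", tag,
                           conditionMessage(e)))
    fs <- tryCatch(fit_candidates(pr),
                   error = function(e)
                     stop_("stage gradient (%s): %s", tag,
                           conditionMessage(e)))
    write_profile_csv(pr, file.path(gdir, paste0("profile_", tag, ".csv")))
    write_fit_json(fs, file.path(gdir, paste0("fit_", tag, ".json")))
    say("gradient %s: %d bins, selected %s (R2 = %.3f)", tag, nrow(pr),
        fs$selected, fs$fits[[fs$selected]]$r2)
    profiles[[tag]] <<- pr; fitsets[[tag]] <<- fs
  }
  for (response in c("rain_reduction", "ndvi_reduction", "resistance",
                     "resilience"))
    run_gradient(px, response, response)
  sub <- subset_by_rain_reduction(px, cfg$subset_rain_reduction[1],
                                  cfg$subset_rain_reduction[2])
  say("subset: %d pixels with rain reduction in [%.2f, %.2f]", nrow(sub),
      cfg$subset_rain_reduction[1], cfg$subset_rain_reduction[2])
  for (response in c("resistance", "resilience"))
    run_gradient(sub, response, paste0(response, "_subset"))

  invisible(list(config = cfg, precip = precip, anomaly = anom,
                 partition = part, stats = stats, metrics = metrics,
                 profiles = profiles, fits = fitsets, output = out_dir))
}
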