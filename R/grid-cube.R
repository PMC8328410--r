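#' Regular geographic grid geometry
#'
#' Describes a regular lon/lat raster grid with square cells,
#' pixel-center registration, row 1 at the northern edge, and
#' coordinates in decimal degrees (WGS84).
#'
#' @param nrow,ncol Grid dimensions (rows run north to south).
#' @param xmin Longitude of the western grid edge (degrees).
#' @param ymax Latitude of the northern grid edge (degrees).
#' @param cellsize Cell size in degrees (cells are square).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrow, ncol, xmin, ymax, cellsize) {
  stopifnot(nrow >= 1, ncol >= 1, is_scalar_number(cellsize), cellsize > 0,
            is_scalar_number(xmin), is_scalar_number(ymax))
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 xmin = xmin, ymax = ymax, cellsize = cellsize),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.5g deg, x [%g, %g], y [%g, %g]\n",
              x$nrow, x$ncol, x$cellsize,
              x$xmin, x$xmin + x$ncol * x$cellsize,
              x$ymax - x$nrow * x$cellsize, x$ymax))
  invisible(x)
}

## Pixel-center coordinates
grid_lon <- function(grid) grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cellsize
grid_lat <- function(grid) grid$ymax - (seq_len(grid$nrow) - 0.5) * grid$cellsize

grids_equal <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Gridded annual raster time series
#'
#' The central raster container: a `(row, col, year)` array of annual
#' values on a [grid_spec()] grid, with a strictly increasing, gapless
#' calendar-year axis. Missing cells are `NA` internally; file-format
#' nodata sentinels are translated on read/write.
#'
#' @param values Numeric array of dim `c(nrow, ncol, n_years)` (a matrix is
#'   accepted for a single year).
#' @param years Integer vector of calendar years, strictly increasing and
#'   gapless.
#' @param grid A [grid_spec()].
#' @param type Optional value domain used for validation: `"ndvi"` restricts
#'   values to `[-1, 1]`, `"precip"` to non-negative; `"unknown"` (default)
#'   applies no range check.
#' @return An object of class `grid_cube`.
#' @export
grid_cube <- function(values, years, grid,
                      type = c("unknown", "ndvi", "precip")) {
  type <- match.arg(type)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  years <- as.integer(years)
  if (length(years) != dim(values)[3])
    stop_("values have %d year slices but %d years given",
          dim(values)[3], length(years))
  check_years_gapless(years)
  if (dim(values)[1] != grid$nrow || dim(values)[2] != grid$ncol)
    stop_("values are %d x %d but grid is %d x %d",
          dim(values)[1], dim(values)[2], grid$nrow, grid$ncol)
  if (any(!is.na(values))) {
    rng <- range(values, na.rm = TRUE)
    if (type == "ndvi" && (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9))
      stop_("NDVI values outside [-1, 1] (range %g..%g)", rng[1], rng[2])
    if (type == "precip" && rng[1] < 0)
      stop_("negative precipitation values (min %g)", rng[1])
  }
  structure(list(values = values, years = years, grid = grid, type = type),
            class = "grid_cube")
}

check_years_gapless <- function(years) {
  if (anyDuplicated(years))
    stop_("duplicate year %d", years[duplicated(years)][1])
  if (is.unsorted(years, strictly = TRUE))
    stop_("years not strictly increasing")
  d <- diff(years)
  if (any(d > 1L))
    stop_("gap at %d", years[which(d > 1L)[1]] + 1L)
  invisible(years)
}

#' @export
print.grid_cube <- function(x, ...) {
  cat(sprintf("<grid_cube> %d x %d pixels, %d years (%d-%d)%s\n",
              x$grid$nrow, x$grid$ncol, length(x$years),
              min(x$years), max(x$years),
              if (x$type == "unknown") "" else paste0(", type ", x$type)))
  cat(sprintf("  missing cells: %d of %d\n", sum(is.na(x$values)),
              length(x$values)))
  invisible(x)
}

#' @export
dim.grid_cube <- function(x) dim(x$values)

## ---- ESRI ASCII grid IO --------------------------------------------------

#' Read / write a single-band ESRI ASCII grid
#'
#' ESRI ASCII (`.asc`) is the plain-text georeferenced raster format used
#' for all file exchange: a six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of values from
#' north to south.
#'
#' @param path File path.
#' @return `read_asc()`: a list with `values` (matrix, `NA` for nodata) and
#'   `grid` (a [grid_spec()]).
#' @export
read_asc <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    ln <- readLines(con, n = 1L)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    } else {
      seek(con, pos); break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop_("%s: malformed ASCII grid header", path)
  nodata <- hdr$nodata_value %||% -9999
  v <- scan(con, what = double(), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(v) != nr * nc)
    stop_("%s: expected %d values, found %d", path, nr * nc, length(v))
  m <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m,
       grid = grid_spec(nr, nc, xmin = hdr$xllcorner,
                        ymax = hdr$yllcorner + nr * hdr$cellsize,
                        cellsize = hdr$cellsize))
}

#' @rdname read_asc
#' @param values Numeric matrix (row 1 = north).
#' @param grid A [grid_spec()] describing `values`.
#' @param nodata Sentinel written for `NA` cells.
#' @export
write_asc <- function(values, grid, path, nodata = -9999) {
  stopifnot(is.matrix(values), nrow(values) == grid$nrow,
            ncol(values) == grid$ncol)
  hdr <- c(sprintf("ncols %d", grid$ncol),
           sprintf("nrows %d", grid$nrow),
           sprintf("xllcorner %.10g", grid$xmin),
           sprintf("yllcorner %.10g", grid$ymax - grid$nrow * grid$cellsize),
           sprintf("cellsize %.10g", grid$cellsize),
           sprintf("NODATA_value %g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a raster time-series stack
#'
#' Reads a directory of single-band ESRI ASCII grids, one per year, with a
#' four-digit year somewhere in each filename, into a [grid_cube()].
#' Years must be gapless and unique and all grids identical.
#'
#' @param path Directory containing `.asc` files.
#' @param type Passed to [grid_cube()] for value-range validation.
#' @param pattern Filename filter (default `"\\.asc$"`).
#' @return A [grid_cube()].
#' @export
read_cube <- function(path, type = "unknown", pattern = "\\.asc$") {
  if (!dir.exists(path)) stop_("%s: not a directory", path)
  files <- list.files(path, pattern = pattern, full.names = TRUE)
  if (!length(files)) stop_("%s: no raster files found", path)
  yrs <- regmatches(basename(files), regexpr("(1[89]|2[01])[0-9]{2}",
                                             basename(files)))
  if (length(yrs) != length(files))
    stop_("some filenames lack a parseable year: %s",
          paste(basename(files)[!grepl("(1[89]|2[01])[0-9]{2}",
                                       basename(files))], collapse = ", "))
  yrs <- as.integer(yrs)
  o <- order(yrs)
  files <- files[o]; yrs <- yrs[o]
  check_years_gapless(yrs)
  first <- read_asc(files[1])
  vals <- array(NA_real_, c(first$grid$nrow, first$grid$ncol, length(files)))
  vals[, , 1] <- first$values
  for (k in seq_along(files)[-1]) {
    a <- read_asc(files[k])
    if (!grids_equal(a$grid, first$grid))
      stop_("%s: grid differs from %s", basename(files[k]), basename(files[1]))
    vals[, , k] <- a$values
  }
  grid_cube(vals, yrs, first$grid, type = type)
}

#' Write a grid cube as a stack of yearly ASCII grids
#'
#' @param cube A [grid_cube()].
#' @param path Output directory (created if absent).
#' @param prefix Filename prefix; files are `<prefix>_<year>.asc`.
#' @inheritParams write_asc
#' @export
write_cube <- function(cube, path, prefix = "band", nodata = -9999) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(cube$years))
    write_asc(cube$values[, , k], cube$grid,
              file.path(path, sprintf("%s_%d.asc", prefix, cube$years[k])),
              nodata = nodata)
  invisible(path)
}

#' Read a 0/1 mask raster
#'
#' @param path An ESRI ASCII grid of 0/1 values.
#' @return A logical matrix (TRUE = keep); attribute `grid` holds the
#'   [grid_spec()].
#' @export
read_mask <- function(path) {
  a <- read_asc(path)
  m <- a$values != 0
  m[is.na(a$values)] <- FALSE
  attr(m, "grid") <- a$grid
  m
}

## ---- composites ----------------------------------------------------------

#' Sub-annual composite NDVI stack
#'
#' Container for 15-day composite imagery prior to annual aggregation:
#' up to 24 composites per calendar year.
#'
#' @param values Array `c(nrow, ncol, n_slices)`.
#' @param slice_year Calendar year of each slice.
#' @param slice_index Within-year composite index (1..24) of each slice.
#' @param grid A [grid_spec()].
#' @export
composite_cube <- function(values, slice_year, slice_index, grid) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            dim(values)[3] == length(slice_year),
            length(slice_year) == length(slice_index),
            all(slice_index >= 1L & slice_index <= 24L))
  if (any(table(slice_year) > 24L))
    stop_("more than 24 composites in a year")
  structure(list(values = values, slice_year = as.integer(slice_year),
                 slice_index = as.integer(slice_index), grid = grid),
            class = "composite_cube")
}

#' Aggregate sub-annual composites to annual means
#'
#' Annual NDVI is the per-pixel mean of the year's non-missing 15-day
#' composites. A pixel-year whose fraction of non-missing composites falls
#' below `min_coverage` is set to missing.
#'
#' @param cube A [composite_cube()].
#' @param min_coverage Minimum fraction of non-missing composites required
#'   for a pixel-year mean (default 0.8).
#' @param type Value domain of the result (default `"ndvi"`).
#' @return A [grid_cube()] of annual means.
#' @export
annual_from_composites <- function(cube, min_coverage = 0.8, type = "ndvi") {
  stopifnot(inherits(cube, "composite_cube"),
            min_coverage >= 0, min_coverage <= 1)
  years <- sort(unique(cube$slice_year))
  check_years_gapless(years)
  out <- array(NA_real_, c(cube$grid$nrow, cube$grid$ncol, length(years)))
  for (k in seq_along(years)) {
    idx <- which(cube$slice_year == years[k])
    if (!length(idx)) stop_("year %d has zero composites", years[k])
    slab <- cube$values[, , idx, drop = FALSE]
    n_ok <- apply(!is.na(slab), c(1, 2), sum)
    mu <- apply(slab, c(1, 2), function(v) mean(v, na.rm = TRUE))
    mu[n_ok / length(idx) < min_coverage | n_ok == 0L] <- NA_real_
    out[, , k] <- mu
  }
  grid_cube(out, years, cube$grid, type = type)
}

## ---- resampling and masking ---------------------------------------------

#' Resample a grid cube onto a target grid
#'
#' Bilinear (default) or nearest-neighbour resampling between regular
#' lon/lat grids in the same CRS. Under bilinear, a target cell whose four
#' contributing source cells include a missing value becomes missing.
#' Target cells outside the source extent are missing; if no target cell
#' overlaps the source extent the call fails.
#'
#' @param cube A [grid_cube()].
#' @param target A [grid_spec()] (or a `grid_cube`, whose grid is used).
#' @param method `"bilinear"` or `"nearest"`.
#' @return A [grid_cube()] on the target grid.
#' @export
resample_to <- function(cube, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (inherits(target, "grid_cube")) target <- target$grid
  stopifnot(inherits(cube, "grid_cube"), inherits(target, "grid_spec"))
  src <- cube$grid
  lon <- grid_lon(target); lat <- grid_lat(target)
  ## fractional (row, col) position of target centers in source index space
  pc <- (lon - src$xmin) / src$cellsize + 0.5
  pr <- (src$ymax - lat) / src$cellsize + 0.5
  inside_c <- pc >= 0.5 & pc <= src$ncol + 0.5
  inside_r <- pr >= 0.5 & pr <= src$nrow + 0.5
  if (!any(inside_r) || !any(inside_c))
    stop_("target extent does not overlap source extent")
  out <- array(NA_real_, c(target$nrow, target$ncol, length(cube$years)))
  if (method == "nearest") {
    ci <- pmin(pmax(round(pc), 1L), src$ncol)
    ri <- pmin(pmax(round(pr), 1L), src$nrow)
    idx <- as.matrix(expand.grid(r = ri, c = ci))
    for (k in seq_along(cube$years)) {
      sl <- cube$values[, , k]
      out[, , k] <- matrix(sl[idx], target$nrow, target$ncol)
    }
  } else {
    ## clamp interpolation positions to the outermost centers
    pcc <- pmin(pmax(pc, 1), src$ncol)
    prr <- pmin(pmax(pr, 1), src$nrow)
    c0 <- pmin(floor(pcc), src$ncol - 1L); c0 <- pmax(c0, 1L)
    r0 <- pmin(floor(prr), src$nrow - 1L); r0 <- pmax(r0, 1L)
    fc <- pcc - c0; fr <- prr - r0
    idx <- as.matrix(expand.grid(r = seq_len(target$nrow),
                                 c = seq_len(target$ncol)))
    R0 <- r0[idx[, "r"]]; C0 <- c0[idx[, "c"]]
    FR <- fr[idx[, "r"]]; FC <- fc[idx[, "c"]]
    for (k in seq_along(cube$years)) {
      sl <- cube$values[, , k]
      v00 <- sl[cbind(R0, C0)];     v01 <- sl[cbind(R0, C0 + 1L)]
      v10 <- sl[cbind(R0 + 1L, C0)]; v11 <- sl[cbind(R0 + 1L, C0 + 1L)]
      val <- (1 - FR) * ((1 - FC) * v00 + FC * v01) +
             FR * ((1 - FC) * v10 + FC * v11)
      m <- matrix(val, target$nrow, target$ncol)
      out[, , k] <- m
    }
  }
  out[!inside_r, , ] <- NA_real_
  out[, !inside_c, ] <- NA_real_
  grid_cube(out, cube$years, target, type = cube$type)
}

#' Restrict a cube to masked cells
#'
#' Cells where the mask is `FALSE` become missing in every year; used to
#' limit the analysis to (e.g.) grassland pixels.
#'
#' @param cube A [grid_cube()].
#' @param mask Logical matrix on the same grid.
#' @export
apply_mask <- function(cube, mask) {
  stopifnot(inherits(cube, "grid_cube"), is.logical(mask) || is.numeric(mask))
  if (!all(dim(mask) == dim(cube$values)[1:2]))
    stop_("mask is %d x %d but cube grid is %d x %d", nrow(mask), ncol(mask),
          cube$grid$nrow, cube$grid$ncol)
  keep <- mask != 0 & !is.na(mask)
  v <- cube$values
  v[!as.vector(keep)] <- NA_real_  # recycles over the year dimension
  grid_cube(v, cube$years, cube$grid, type = cube$type)
}
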