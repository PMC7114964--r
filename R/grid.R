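#' Georeferenced raster grid
#'
#' A `moundr_grid` is a minimal in-memory raster: a numeric matrix of cell
#' values (row 1 is the northernmost row), a square cell size in metres, the
#' coordinates of the lower-left corner of the grid, and an opaque CRS tag.
#' Elevation grids are stored up-positive, so seabed depths are negative
#' values; `NA` cells are nodata.
#'
#' @param values numeric matrix; row 1 = northernmost row, column 1 = western
#'   edge. `NA` marks nodata.
#' @param cell_size cell edge length in metres (square cells, > 0).
#' @param xll,yll coordinates of the outer lower-left corner of the grid.
#' @param crs opaque projected-CRS identifier, copied verbatim to derived
#'   rasters.
#' @return an object of class `moundr_grid`.
#' @export
grid_create <- function(values, cell_size, xll = 0, yll = 0, crs = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values present; use NA for nodata")
  g <- structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll), crs = as.character(crs)),
    class = "moundr_grid")
  g
}

#' @method print moundr_grid
#' @export
print.moundr_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<moundr_grid> %d rows x %d cols @ %g m\n", d[1], d[2], x$cell_size))
  cat(sprintf("  lower-left corner: (%g, %g)%s\n", x$xll, x$yll,
              if (nzchar(x$crs)) paste0("  crs: ", x$crs) else ""))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

is_grid <- function(x) inherits(x, "moundr_grid")

stopifnot_grid <- function(x, what = "grid") {
  if (!is_grid(x)) stop(sprintf("`%s` must be a moundr_grid", what))
  invisible(x)
}

#' Cell-centre coordinates
#'
#' Map between matrix indices and projected coordinates. Cell (r, c) has its
#' centre at `x = xll + (c - 0.5) * cell_size`,
#' `y = yll + (nrow - r + 0.5) * cell_size`.
#'
#' @param grid a `moundr_grid`.
#' @param row,col matrix indices (vectorised).
#' @return `cell_center()`: a two-column matrix of x/y coordinates.
#' @export
cell_center <- function(grid, row, col) {
  stopifnot_grid(grid)
  nr <- nrow(grid$values)
  cbind(x = grid$xll + (col - 0.5) * grid$cell_size,
        y = grid$yll + (nr - row + 0.5) * grid$cell_size)
}

#' @rdname cell_center
#' @param x,y projected coordinates (vectorised).
#' @return `cell_at()`: a two-column integer matrix of row/col indices; cells
#'   outside the grid extent are `NA`.
#' @export
cell_at <- function(grid, x, y) {
  stopifnot_grid(grid)
  d <- dim(grid$values)
  col <- floor((x - grid$xll) / grid$cell_size) + 1L
  row <- d[1] - floor((y - grid$yll) / grid$cell_size)
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read a raster grid
#'
#' Reads an ESRI ASCII grid (`.asc`) into a [grid_create()] object. The header
#' must carry `ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/
#' `yllcenter` and `cellsize`; cells equal to the declared `NODATA_value`
#' become `NA`. GeoTIFF is not supported by this build and raises an error.
#'
#' @param path file path.
#' @param format `"esri_ascii"` or `"geotiff"`.
#' @param depth_positive if `TRUE` the file stores depths as positive-down
#'   metres and values are negated on read to the up-positive convention.
#' @param crs CRS tag to attach (ESRI ASCII carries none itself).
#' @return a `moundr_grid`.
#' @export
read_raster <- function(path, format = c("esri_ascii", "geotiff"),
                        depth_positive = FALSE, crs = "") {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF I/O is not supported by this build; ",
         "convert to ESRI ASCII grid (e.g. gdal_translate -of AAIGrid)")
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path, n = 8L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)) ||
      !any(c("xllcorner", "xllcenter") %in% names(hdr)) ||
      !any(c("yllcorner", "yllcenter") %in% names(hdr)))
    stop("not a valid ESRI ASCII grid (missing georeferencing header): ", path)
  if (!is.null(hdr$dx) || !is.null(hdr$dy))
    stop("non-square cells are not supported: ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d: %s", nr * nc, length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  if (depth_positive) m <- -m
  grid_create(m, cs, xll, yll, crs)
}

#' Write a raster grid
#'
#' Writes a `moundr_grid` as an ESRI ASCII grid with full double precision
#' (`%.17g`), so a write/read round trip reproduces values bit-exactly.
#'
#' @param grid a `moundr_grid`.
#' @param path output path.
#' @param format only `"esri_ascii"` is supported.
#' @param nodata numeric sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = c("esri_ascii", "geotiff"),
                         nodata = -9999) {
  stopifnot_grid(grid)
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF I/O is not supported by this build; writing ESRI ASCII only")
  m <- grid$values
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.17g", grid$xll),
    sprintf("yllcorner %.17g", grid$yll),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", nodata)), con)
  for (r in seq_len(nrow(m)))
    writeLines(paste(sprintf("%.17g", m[r, ]), collapse = " "), con)
  invisible(path)
}

# derive a new grid sharing georeferencing with `grid`
grid_like <- function(grid, values) {
  grid_create(values, grid$cell_size, grid$xll, grid$yll, grid$crs)
}
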