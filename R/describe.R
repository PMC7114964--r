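# flood fill (8-connected) from a seed over a logical matrix
flood_from <- function(mask, seed) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  if (!mask[seed]) return(out)
  out[seed] <- TRUE
  frontier <- seed
  offs <- expand.grid(dr = -1L:1L, dc = -1L:1L)
  offs <- offs[!(offs$dr == 0L & offs$dc == 0L), ]
  while (length(frontier)) {
    r <- ((frontier - 1L) %% nr) + 1L
    c <- ((frontier - 1L) %/% nr) + 1L
    nxt <- integer(0)
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      if (!any(ok)) next
      ni <- (cc[ok] - 1L) * nr + rr[ok]
      ni <- ni[mask[ni] & !out[ni]]
      if (length(ni)) { out[ni] <- TRUE; nxt <- c(nxt, ni) }
    }
    frontier <- unique(nxt)
  }
  out
}

# Depth of the deepest contour (at `interval` spacing, levels anchored at
# multiples of the interval) that closes entirely inside the feature's cell
# set and encloses the summit cell. Returns positive-down metres, or NA when
# no contour level is confined.
confined_contour_depth <- function(z, cells, interval) {
  nr <- nrow(z)
  zc <- z[cells]
  if (all(is.na(zc))) return(NA_real_)
  summit <- cells[which.max(zc)]
  r <- ((cells - 1L) %% nr) + 1L
  c <- ((cells - 1L) %/% nr) + 1L
  r0 <- max(1L, min(r) - 1L); r1 <- min(nrow(z), max(r) + 1L)
  c0 <- max(1L, min(c) - 1L); c1 <- min(ncol(z), max(c) + 1L)
  sub <- z[r0:r1, c0:c1, drop = FALSE]
  snr <- nrow(sub)
  in_feat <- matrix(FALSE, snr, ncol(sub))
  in_feat[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE
  sr <- ((summit - 1L) %% nr) + 1L
  sc <- ((summit - 1L) %/% nr) + 1L
  sseed <- (sc - c0) * snr + (sr - r0 + 1L)
  z_summit <- max(zc, na.rm = TRUE)
  zmin <- min(sub, na.rm = TRUE)
  lev <- interval * floor(z_summit / interval)
  deepest <- NA_real_
  while (lev >= zmin - interval) {
    mask <- !is.na(sub) & sub >= lev
    comp <- flood_from(mask, sseed)
    if (any(comp & !in_feat)) break     # contour escapes the outline
    deepest <- lev
    lev <- lev - interval
  }
  if (is.na(deepest)) NA_real_ else -deepest
}

#' Reconstructed pre-mound seabed slope
#'
#' Estimates the slope of the seabed as it presumably was before the mound
#' grew: the elevations inside the feature outline are removed and the gap is
#' refilled by harmonic (Laplace) interpolation with the surrounding cells as
#' a fixed boundary, solving the 5-point discrete Laplace system exactly with
#' a sparse direct solver. The returned value is the mean Horn slope (decimal
#' degrees) of the reconstructed surface over the voided cells. Harmonic
#' infill reproduces planar surfaces exactly, so a mound planted on a uniform
#' slope recovers that slope.
#'
#' @param dem a `moundr_grid` of elevations.
#' @param feature one feature from [delineate()] (needs `$cells`), or a list
#'   with a `cells` element of linear cell indices into `dem`.
#' @return mean slope of the reconstructed surface inside the feature, in
#'   decimal degrees.
#' @export
initial_slope <- function(dem, feature) {
  stopifnot_grid(dem)
  cells <- feature$cells
  if (is.null(cells) || !length(cells))
    stop("feature polygon covers no cells")
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  r <- ((cells - 1L) %% nr) + 1L
  c <- ((cells - 1L) %/% nr) + 1L
  if (any(r <= 1L | r >= nr | c <= 1L | c >= nc))
    stop("feature touches the raster edge: no closed boundary for interpolation")
  n <- length(cells)
  idx_of <- integer(nr * nc)
  idx_of[cells] <- seq_len(n)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  b <- numeric(n)
  steps <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (s in steps) {
    nb <- (c + s[2] - 1L) * nr + (r + s[1])
    isvoid <- idx_of[nb] > 0L
    ii <- c(ii, which(isvoid)); jj <- c(jj, idx_of[nb[isvoid]])
    xx <- c(xx, rep(-1, sum(isvoid)))
    known <- !isvoid
    if (any(is.na(z[nb[known]])))
      stop("feature boundary contains nodata cells: no closed boundary")
    b[which(known)] <- b[which(known)] + z[nb[known]]
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, rep(4, n)), dims = c(n, n))
  sol <- as.numeric(Matrix::solve(A, b))
  # rebuild a local patch (one-cell margin) and take the Horn slope there
  r0 <- min(r) - 1L; r1 <- max(r) + 1L
  c0 <- min(c) - 1L; c1 <- max(c) + 1L
  patch <- z[r0:r1, c0:c1, drop = FALSE]
  patch[cbind(r - r0 + 1L, c - c0 + 1L)] <- sol
  sl <- slope(grid_create(patch, dem$cell_size))$values
  mean(sl[cbind(r - r0 + 1L, c - c0 + 1L)], na.rm = TRUE)
}

# zonal summary of one raster layer over a cell index set
zonal_stats <- function(values, cells) {
  v <- values[cells]
  v <- v[!is.na(v)]
  if (!length(v)) return(c(min = NA_real_, max = NA_real_, mean = NA_real_))
  c(min = min(v), max = max(v), mean = mean(v))
}

#' Characterise delineated features
#'
#' Computes the standard attribute record for every delineated feature:
#' polygon area and perimeter, maximum BPI, minimum-bounding-rectangle width,
#' length, width/length ratio and orientation, minimum/mean/maximum water
#' depth (positive-down metres), the depth of the deepest confined contour
#' line (`ConfCL_WD`), minimum and maximum vertical relief
#' (`MaxVRelief = MaxWD - MinWD`; `MinVRelief = ConfCL_WD - MinWD`, the relief
#' of the summit above the deepest contour closing inside the outline),
#' rugosity and (optionally) backscatter zonal statistics, and the
#' reconstructed pre-mound slope ([initial_slope()]). Zonal statistics are
#' taken over the cells of the buffered outline.
#'
#' @param dem elevation `moundr_grid` (up-positive).
#' @param bpi BPI `moundr_grid` co-registered with `dem`.
#' @param features a `mound_features` object from [delineate()].
#' @param rugosity_grid rugosity `moundr_grid` co-registered with `dem`
#'   (default: `rugosity(dem)`).
#' @param backscatter optional backscatter `moundr_grid`; when absent the
#'   `*_BS` columns are `NA`.
#' @param contour_interval contour spacing in metres for `ConfCL_WD`
#'   (default 0.5).
#' @param with_initial_slope compute `InitialSlp` (set `FALSE` to skip the
#'   interpolation, e.g. for very large batches).
#' @return a `data.frame` with one row per feature and columns `feature_id`,
#'   `Area`, `Perimeter`, `Index`, `MBG_Width`, `MBG_Length`, `MBG_W_L`,
#'   `MBG_Orient`, `MinWD`, `MaxWD`, `MeanWD`, `ConfCL_WD`, `MinVRelief`,
#'   `MaxVRelief`, `Min_Rug`, `Max_Rug`, `Mean_Rug`, `Min_BS`, `Max_BS`,
#'   `Mean_BS`, `InitialSlp`, `merged_flag`, `centroid_x`, `centroid_y`.
#' @export
describe_features <- function(dem, bpi, features, rugosity_grid = NULL,
                              backscatter = NULL, contour_interval = 0.5,
                              with_initial_slope = TRUE) {
  stopifnot_grid(dem); stopifnot_grid(bpi, "bpi")
  if (!inherits(features, "mound_features"))
    stop("`features` must be a mound_features object")
  if (!identical(dim(dem$values), dim(bpi$values)))
    stop("dem and bpi are not co-registered")
  if (is.null(rugosity_grid)) rugosity_grid <- rugosity(dem)
  if (!identical(dim(dem$values), dim(rugosity_grid$values)))
    stop("dem and rugosity_grid are not co-registered")
  if (!is.null(backscatter) && !identical(dim(dem$values), dim(backscatter$values)))
    stop("dem and backscatter are not co-registered")
  nr <- nrow(dem$values)
  cs <- dem$cell_size
  rows <- lapply(features$features, function(f) {
    cells <- f$cells
    if (is.null(cells) || !length(cells)) {
      warning(sprintf("feature %s contains no cell centres; attributes are NA",
                      f$feature_id))
      return(data.frame(feature_id = f$feature_id, Area = NA_real_,
                        Perimeter = NA_real_, Index = NA_real_,
                        MBG_Width = NA_real_, MBG_Length = NA_real_,
                        MBG_W_L = NA_real_, MBG_Orient = NA_real_,
                        MinWD = NA_real_, MaxWD = NA_real_, MeanWD = NA_real_,
                        ConfCL_WD = NA_real_, MinVRelief = NA_real_,
                        MaxVRelief = NA_real_, Min_Rug = NA_real_,
                        Max_Rug = NA_real_, Mean_Rug = NA_real_,
                        Min_BS = NA_real_, Max_BS = NA_real_, Mean_BS = NA_real_,
                        InitialSlp = NA_real_, merged_flag = isTRUE(f$merged_flag),
                        centroid_x = NA_real_, centroid_y = NA_real_))
    }
    zst <- zonal_stats(dem$values, cells)
    rst <- zonal_stats(rugosity_grid$values, cells)
    bst <- if (is.null(backscatter)) c(min = NA_real_, max = NA_real_, mean = NA_real_)
           else zonal_stats(backscatter$values, cells)
    mbr <- min_bounding_rectangle(f$ring)
    confcl <- confined_contour_depth(dem$values, cells, contour_interval)
    min_wd <- -zst["max"]; max_wd <- -zst["min"]; mean_wd <- -zst["mean"]
    islp <- if (with_initial_slope)
      tryCatch(initial_slope(dem, f), error = function(e) {
        warning(sprintf("feature %s: %s", f$feature_id, conditionMessage(e)))
        NA_real_
      }) else NA_real_
    ctr <- colMeans(cell_center(dem,
                                ((cells - 1L) %% nr) + 1L,
                                ((cells - 1L) %/% nr) + 1L))
    data.frame(
      feature_id = f$feature_id,
      Area = length(cells) * cs^2,
      Perimeter = polygon_perimeter(f$ring),
      Index = max(bpi$values[cells], na.rm = TRUE),
      MBG_Width = mbr$width, MBG_Length = mbr$length,
      MBG_W_L = mbr$w_l, MBG_Orient = mbr$orient,
      MinWD = unname(min_wd), MaxWD = unname(max_wd), MeanWD = unname(mean_wd),
      ConfCL_WD = confcl,
      MinVRelief = unname(confcl - min_wd),
      MaxVRelief = unname(max_wd - min_wd),
      Min_Rug = unname(rst["min"]), Max_Rug = unname(rst["max"]),
      Mean_Rug = unname(rst["mean"]),
      Min_BS = unname(bst["min"]), Max_BS = unname(bst["max"]),
      Mean_BS = unname(bst["mean"]),
      InitialSlp = islp,
      merged_flag = isTRUE(f$merged_flag),
      centroid_x = ctr[["x"]], centroid_y = ctr[["y"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Join coarse current-speed data onto feature records
#'
#' The current raster is typically far coarser than the bathymetry (here
#' 100 x 100 m vs 2 x 2 m), so each feature simply receives the current value
#' at the raster cell containing its centroid, mirroring an attribute join.
#'
#' @param attributes data.frame from [describe_features()] (needs
#'   `centroid_x`/`centroid_y`).
#' @param current a `moundr_grid` of maximum current speed (m s^-1).
#' @return `attributes` with a `MaxCurrent` column appended.
#' @export
join_current <- function(attributes, current) {
  stopifnot_grid(current, "current")
  rc <- cell_at(current, attributes$centroid_x, attributes$centroid_y)
  out <- rep(NA_real_, nrow(attributes))
  ok <- !is.na(rc[, "row"])
  if (any(!ok))
    warning(sprintf("%d feature centroid(s) outside the current raster extent",
                    sum(!ok)))
  out[ok] <- current$values[rc[ok, , drop = FALSE]]
  attributes$MaxCurrent <- out
  attributes
}

# close an open ring, warn-and-repair
close_ring <- function(ring, name = "polygon") {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L || nrow(ring) < 3L)
    stop("invalid coral ", name, ": need a two-column matrix of >= 3 vertices")
  if (any(!is.finite(ring))) stop("invalid coral ", name, ": non-finite vertex")
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' Live-coral cover per feature
#'
#' Intersects each feature outline with a layer of manually mapped live-coral
#' polygons and reports the percent cover and the five-bin cover class
#' (`=0`, `]0;25]`, `]25;50]`, `]50;75]`, `]75;100]`; intervals left-exclusive
#' and right-inclusive). The overlay area is evaluated by dense point
#' sampling: every feature cell is subdivided into `subsamples x subsamples`
#' points tested against the coral polygons (even-odd rule, union across
#' polygons), so at the default 5 the sampling pitch is cell_size/5.
#'
#' @param features a `mound_features` object.
#' @param coral_polygons a list of closed two-column rings (x, y) in the same
#'   CRS as the features, or a single such matrix. Open rings are closed with
#'   a repair.
#' @param subsamples sampling density per cell edge (default 5).
#' @return data.frame with `feature_id`, `CoverPct`, `CoverClass`, `presence`.
#' @export
cover_class <- function(features, coral_polygons, subsamples = 5L) {
  if (!inherits(features, "mound_features"))
    stop("`features` must be a mound_features object")
  if (is.matrix(coral_polygons)) coral_polygons <- list(coral_polygons)
  coral_polygons <- lapply(seq_along(coral_polygons), function(i)
    close_ring(coral_polygons[[i]], paste0("polygon ", i)))
  geo <- features$grid
  s <- as.integer(subsamples)
  frac <- (seq_len(s) - 0.5) / s
  rows <- lapply(features$features, function(f) {
    cells <- f$cells
    r <- ((cells - 1L) %% geo$nrow) + 1L
    c <- ((cells - 1L) %/% geo$nrow) + 1L
    x0 <- geo$xll + (c - 1L) * geo$cell_size
    y0 <- geo$yll + (geo$nrow - r) * geo$cell_size
    px <- rep(x0, each = s * s) +
      rep(rep(frac, times = s), times = length(cells)) * geo$cell_size
    py <- rep(y0, each = s * s) +
      rep(rep(frac, each = s), times = length(cells)) * geo$cell_size
    pts <- cbind(px, py)
    inside <- rep(FALSE, nrow(pts))
    for (ring in coral_polygons)
      inside <- inside | mgcv::in.out(ring, pts)
    pct <- 100 * mean(inside)
    data.frame(feature_id = f$feature_id, CoverPct = pct,
               CoverClass = classify_cover(pct), presence = pct > 0)
  })
  do.call(rbind, rows)
}

#' @rdname cover_class
#' @param pct percent cover in \[0, 100\] (vectorised).
#' @export
classify_cover <- function(pct) {
  out <- character(length(pct))
  out[pct <= 0] <- "=0"
  out[pct > 0  & pct <= 25]  <- "]0;25]"
  out[pct > 25 & pct <= 50]  <- "]25;50]"
  out[pct > 50 & pct <= 75]  <- "]50;75]"
  out[pct > 75 & pct <= 100] <- "]75;100]"
  out[is.na(pct)] <- NA_character_
  out
}
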