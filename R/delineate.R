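#' Delineation thresholds
#'
#' The user-set thresholds of the feature delineation step: candidate regions
#' are grown from cells with BPI >= `cutline_bpi`, and a region is kept only
#' if its maximum BPI reaches `min_bpi`, its area reaches `min_area` and the
#' width/length ratio of its minimum-area bounding rectangle reaches
#' `min_wl_ratio`. Surviving outlines are expanded outward by
#' `buffer_distance` (cosmetic: filters are applied before buffering).
#' Defaults are the thresholds used for the Mingulay mini-mounds
#' (3 / 3.5 / 50 m^2 / 0.2 / 4 m).
#'
#' @param cutline_bpi BPI threshold that seeds region growing.
#' @param min_bpi minimum of the region's maximum BPI (`>= cutline_bpi`).
#' @param min_area minimum raw region area in m^2.
#' @param min_wl_ratio minimum bounding-rectangle width/length ratio in (0, 1].
#' @param buffer_distance outward expansion in metres (>= 0).
#' @return an object of class `delineation_config`.
#' @export
delineation_config <- function(cutline_bpi = 3, min_bpi = 3.5, min_area = 50,
                               min_wl_ratio = 0.2, buffer_distance = 4) {
  if (min_bpi < cutline_bpi) stop("min_bpi must be >= cutline_bpi")
  if (min_area <= 0) stop("min_area must be positive")
  if (min_wl_ratio <= 0 || min_wl_ratio > 1) stop("min_wl_ratio must be in (0, 1]")
  if (buffer_distance < 0) stop("buffer_distance must be >= 0")
  structure(list(cutline_bpi = cutline_bpi, min_bpi = min_bpi,
                 min_area = min_area, min_wl_ratio = min_wl_ratio,
                 buffer_distance = buffer_distance),
            class = "delineation_config")
}

# 8-connected labelling of a logical matrix; returns integer matrix, 0 = bg.
# Regions are numbered in order of their smallest linear index, so labelling
# is deterministic.
label_regions <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  todo <- which(mask)
  if (!length(todo)) return(labels)
  offs <- expand.grid(dr = -1L:1L, dc = -1L:1L)
  offs <- offs[!(offs$dr == 0L & offs$dc == 0L), ]
  lab <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        ni <- (cc[ok] - 1L) * nr + rr[ok]
        ni <- ni[mask[ni] & labels[ni] == 0L]
        if (length(ni)) {
          labels[ni] <- lab
          nxt <- c(nxt, ni)
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

#' Minimum-area bounding rectangle
#'
#' Rotating-calipers rectangle over the convex hull of a point set. `width` is
#' the shorter side, `length` the longer; `orient` is the azimuth of the long
#' axis, clockwise from grid north, reported in \[0, 180) (0 for a tie
#' between the sides).
#'
#' @param pts two-column matrix of x/y coordinates (>= 2 distinct points).
#' @return list with `width`, `length`, `w_l`, `orient`, `area`.
#' @export
min_bounding_rectangle <- function(pts) {
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  if (nrow(pts) < 2L) stop("need at least two distinct points")
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  best <- NULL
  for (k in seq_len(n)) {
    p1 <- hull[k, ]; p2 <- hull[if (k == n) 1L else k + 1L, ]
    e <- p2 - p1
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len                 # along edge
    v <- c(-u[2], u[1])          # perpendicular
    proj_u <- hull[, 1] * u[1] + hull[, 2] * u[2]
    proj_v <- hull[, 1] * v[1] + hull[, 2] * v[2]
    du <- diff(range(proj_u)); dv <- diff(range(proj_v))
    if (is.null(best) || du * dv < best$area - 1e-12)
      best <- list(area = du * dv, du = du, dv = dv, u = u, v = v)
  }
  if (is.null(best)) stop("degenerate point set")
  if (best$du >= best$dv) { len <- best$du; wid <- best$dv; axis <- best$u }
  else                    { len <- best$dv; wid <- best$du; axis <- best$v }
  orient <- if (abs(len - wid) < 1e-12) 0
            else (atan2(axis[1], axis[2]) * 180 / pi) %% 180
  list(width = wid, length = len,
       w_l = if (len > 0) wid / len else NA_real_,
       orient = orient, area = best$area)
}

# corner points (4 per cell) of a set of cells given as linear indices
cell_corner_points <- function(cells, nr, cell_size, xll, yll) {
  r <- ((cells - 1L) %% nr) + 1L
  c <- ((cells - 1L) %/% nr) + 1L
  x0 <- xll + (c - 1L) * cell_size; x1 <- x0 + cell_size
  y1 <- yll + (nr - r + 1L) * cell_size; y0 <- y1 - cell_size
  cbind(x = c(x0, x0, x1, x1), y = c(y0, y1, y0, y1))
}

# dilate a cell set (linear indices) by a Euclidean radius in cell units
dilate_cells <- function(cells, nr, nc, radius_cells) {
  if (radius_cells <= 0) return(sort(cells))
  k <- floor(radius_cells)
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_cells^2, ]
  r <- ((cells - 1L) %% nr) + 1L
  c <- ((cells - 1L) %/% nr) + 1L
  out <- integer(0)
  for (i in seq_len(nrow(offs))) {
    rr <- r + offs$dr[i]; cc <- c + offs$dc[i]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    out <- c(out, (cc[ok] - 1L) * nr + rr[ok])
  }
  sort(unique(out))
}

# Trace the boundary of a cell set into closed rings along cell edges.
# Returns the outer ring (largest absolute area) as a closed two-column
# matrix in CRS coordinates, counterclockwise (interior on the left).
trace_outer_ring <- function(cells, nr, nc, cell_size, xll, yll) {
  inset <- logical(nr * nc); inset[cells] <- TRUE
  r <- ((cells - 1L) %% nr) + 1L
  c <- ((cells - 1L) %/% nr) + 1L
  vid <- function(i, j) i * (nc + 1L) + j + 1L   # corner (i, j); i in 0..nr, j in 0..nc
  has <- function(rr, cc) rr >= 1L & rr <= nr & cc >= 1L & cc <= nc &
    inset[pmax(1L, (cc - 1L) * nr + rr)] & !(rr < 1L | rr > nr | cc < 1L | cc > nc)
  nbr <- function(dr, dc) {
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    out <- logical(length(r))
    out[ok] <- inset[(cc[ok] - 1L) * nr + rr[ok]]
    out
  }
  # directed boundary edges, interior on the left (grid y is up => row 0 = top)
  from <- integer(0); to <- integer(0)
  e_top <- !nbr(-1L, 0L)   # top side exposed: TR -> TL
  from <- c(from, vid(r[e_top] - 1L, c[e_top]))
  to   <- c(to,   vid(r[e_top] - 1L, c[e_top] - 1L))
  e_left <- !nbr(0L, -1L)  # left side: TL -> BL
  from <- c(from, vid(r[e_left] - 1L, c[e_left] - 1L))
  to   <- c(to,   vid(r[e_left], c[e_left] - 1L))
  e_bot <- !nbr(1L, 0L)    # bottom side: BL -> BR
  from <- c(from, vid(r[e_bot], c[e_bot] - 1L))
  to   <- c(to,   vid(r[e_bot], c[e_bot]))
  e_right <- !nbr(0L, 1L)  # right side: BR -> TR
  from <- c(from, vid(r[e_right], c[e_right]))
  to   <- c(to,   vid(r[e_right] - 1L, c[e_right]))
  ne <- length(from)
  used <- logical(ne)
  # outgoing edge lists per start vertex
  ord <- order(from)
  starts <- from[ord]
  first <- match(unique(starts), starts)
  out_idx <- split(ord, from[ord])
  corner_xy <- function(v) {
    i <- (v - 1L) %/% (nc + 1L); j <- (v - 1L) %% (nc + 1L)
    c(xll + j * cell_size, yll + (nr - i) * cell_size)
  }
  edge_dir <- function(k) {
    a <- corner_xy(from[k]); b <- corner_xy(to[k])
    b - a
  }
  rings <- list()
  for (k0 in seq_len(ne)) {
    if (used[k0]) next
    ring_v <- from[k0]
    k <- k0
    repeat {
      used[k] <- TRUE
      ring_v <- c(ring_v, to[k])
      if (to[k] == ring_v[1L]) break
      cand <- out_idx[[as.character(to[k])]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break  # should not happen on a valid boundary
      if (length(cand) > 1L) {
        # pinch vertex: prefer the leftmost turn (keeps interior on the left)
        d_in <- edge_dir(k)
        score <- vapply(cand, function(kk) {
          d <- edge_dir(kk)
          atan2(d_in[1] * d[2] - d_in[2] * d[1], d_in[1] * d[1] + d_in[2] * d[2])
        }, numeric(1))
        k <- cand[which.max(score)]
      } else k <- cand
    }
    xy <- t(vapply(ring_v, corner_xy, numeric(2)))
    colnames(xy) <- c("x", "y")
    rings[[length(rings) + 1L]] <- xy
  }
  areas <- vapply(rings, function(p) abs(polygon_area(p)), numeric(1))
  rings[[which.max(areas)]]
}

#' Polygon area and perimeter
#'
#' Shoelace area (positive for counterclockwise rings) and boundary length of
#' a closed ring given as a two-column coordinate matrix whose first and last
#' vertices coincide.
#'
#' @param ring closed two-column matrix of vertices.
#' @return a single number.
#' @export
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' @rdname polygon_area
#' @export
polygon_perimeter <- function(ring) {
  sum(sqrt(rowSums(diff(ring)^2)))
}

#' Delineate positive-relief features from a BPI raster
#'
#' Implements the feature delineation workflow: (1) threshold cells with
#' BPI >= `cutline_bpi`; (2) group them into 8-connected regions; (3) discard
#' regions whose maximum BPI is below `min_bpi`, whose area is below
#' `min_area`, or whose minimum-bounding-rectangle width/length ratio is below
#' `min_wl_ratio`; (4) trace each surviving region into a polygon along cell
#' boundaries; (5) expand it outward by `buffer_distance` (Euclidean dilation
#' on the grid). Buffered outlines that touch or overlap a neighbour are NOT
#' dissolved: each feature keeps its identity with `merged_flag = TRUE`, for
#' manual resolution downstream.
#'
#' @param bpi a `moundr_grid` of BPI values (see [compute_bpi()]).
#' @param config a [delineation_config()].
#' @return an object of class `mound_features`: a list with `features` (a list
#'   of feature polygons, each with `feature_id`, `ring`, `raw_ring`, `cells`,
#'   `raw_cells`, `merged_flag`, `edited_flag`), `grid` (georeferencing) and
#'   `config`.
#' @export
delineate <- function(bpi, config = delineation_config()) {
  stopifnot_grid(bpi)
  if (!inherits(config, "delineation_config"))
    stop("`config` must be a delineation_config")
  Z <- bpi$values
  nr <- nrow(Z); nc <- ncol(Z)
  cs <- bpi$cell_size
  geo <- list(nrow = nr, ncol = nc, cell_size = cs,
              xll = bpi$xll, yll = bpi$yll, crs = bpi$crs)
  empty <- structure(list(features = list(), grid = geo, config = config),
                     class = "mound_features")
  if (all(is.na(Z))) {
    warning("BPI raster is entirely nodata; no features delineated")
    return(empty)
  }
  mask <- !is.na(Z) & Z >= config$cutline_bpi
  if (!any(mask)) return(empty)
  labels <- label_regions(mask)
  nlab <- max(labels)
  feats <- list()
  for (lab in seq_len(nlab)) {
    raw_cells <- which(labels == lab)
    if (max(Z[raw_cells]) < config$min_bpi) next
    if (length(raw_cells) * cs^2 < config$min_area) next
    mbr <- min_bounding_rectangle(
      cell_corner_points(raw_cells, nr, cs, geo$xll, geo$yll))
    if (mbr$w_l < config$min_wl_ratio) next
    feats[[length(feats) + 1L]] <- list(raw_cells = raw_cells)
  }
  if (!length(feats)) return(empty)
  rad <- config$buffer_distance / cs
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    f$feature_id <- i
    f$cells <- dilate_cells(f$raw_cells, nr, nc, rad)
    f$raw_ring <- trace_outer_ring(f$raw_cells, nr, nc, cs, geo$xll, geo$yll)
    f$ring <- if (rad > 0)
      trace_outer_ring(f$cells, nr, nc, cs, geo$xll, geo$yll) else f$raw_ring
    f$merged_flag <- FALSE
    f$edited_flag <- FALSE
    feats[[i]] <- f
  }
  # flag buffered outlines that touch/overlap a neighbour (8-adjacency)
  if (length(feats) > 1L) {
    expanded <- lapply(feats, function(f) dilate_cells(f$cells, nr, nc, sqrt(2)))
    for (i in seq_along(feats)) for (j in seq_along(feats)) {
      if (i >= j) next
      if (length(intersect(expanded[[i]], feats[[j]]$cells))) {
        feats[[i]]$merged_flag <- TRUE
        feats[[j]]$merged_flag <- TRUE
      }
    }
  }
  structure(list(features = feats, grid = geo, config = config),
            class = "mound_features")
}

#' @method print mound_features
#' @export
print.mound_features <- function(x, ...) {
  cat(sprintf("<mound_features> %d features (cell size %g m)\n",
              length(x$features), x$grid$cell_size))
  nm <- sum(vapply(x$features, function(f) f$merged_flag, logical(1)))
  if (nm) cat(sprintf("  %d flagged as touching a neighbour after buffering\n", nm))
  invisible(x)
}

#' @export
length.mound_features <- function(x) length(x$features)
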