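#' Annular neighbourhood specification
#'
#' Defines the ring of cells used by [focal_mean_annulus()] and
#' [compute_bpi()]. A cell at offset (dx, dy) from the centre belongs to the
#' annulus when its centre-to-centre Euclidean distance `d = sqrt(dx^2 + dy^2)`
#' (in cell units) satisfies `inner <= d <= outer`, bounds inclusive.
#'
#' @param inner,outer inner and outer radii in cells; integers with
#'   `outer > inner >= 1`.
#' @return an object of class `annulus_spec`.
#' @export
annulus_spec <- function(inner = 8L, outer = 24L) {
  inner <- as.integer(inner); outer <- as.integer(outer)
  if (is.na(inner) || is.na(outer) || inner < 1L || outer <= inner)
    stop("annulus requires integer radii with outer > inner >= 1")
  structure(list(inner = inner, outer = outer), class = "annulus_spec")
}

#' @method print annulus_spec
#' @export
print.annulus_spec <- function(x, ...) {
  cat(sprintf("<annulus_spec> i%d x o%d (%d member cells)\n",
              x$inner, x$outer, annulus_n_cells(x)))
  invisible(x)
}

# per-dy runs of member dx offsets; list indexed by dy = -outer..outer
annulus_runs <- function(annulus) {
  inner <- annulus$inner; outer <- annulus$outer
  runs <- vector("list", 2L * outer + 1L)
  for (dy in -outer:outer) {
    dxmax <- floor(sqrt(outer^2 - dy^2))
    hole <- inner^2 - dy^2          # d < inner  <=>  dx^2 < hole
    if (hole > 0) {
      ex <- ceiling(sqrt(hole)) - 1L   # largest |dx| strictly inside the hole
      if (ex^2 >= hole) ex <- ex - 1L  # guard exact squares: dx^2 == hole is a member
      if (ex + 1L <= dxmax)
        runs[[dy + outer + 1L]] <- rbind(c(-dxmax, -(ex + 1L)), c(ex + 1L, dxmax))
      else runs[[dy + outer + 1L]] <- NULL
    } else {
      runs[[dy + outer + 1L]] <- rbind(c(-dxmax, dxmax))
    }
  }
  runs
}

# number of member offsets in the annulus
annulus_n_cells <- function(annulus) {
  sum(vapply(annulus_runs(annulus), function(r) {
    if (is.null(r)) 0L else as.integer(sum(r[, 2] - r[, 1] + 1L))
  }, integer(1)))
}

# row-wise running sums with a leading zero column: out[, j + 1] = sum(m[, 1:j])
row_cumsum0 <- function(m) {
  cbind(0, t(apply(m, 1L, cumsum)))
}

#' Focal mean over an annular neighbourhood
#'
#' For every cell, the mean of the valid cells whose centre lies within the
#' annulus (see [annulus_spec()]). Cells beyond the grid edge and nodata cells
#' do not contribute; a cell whose valid-neighbour fraction falls below
#' `min_valid_fraction` becomes nodata in the output.
#'
#' Internally the grid is globally demeaned before summation (and the mean
#' added back), which makes the result exactly invariant under adding a
#' constant to all elevations.
#'
#' @param grid a `moundr_grid`.
#' @param annulus an [annulus_spec()].
#' @param min_valid_fraction minimum fraction of the full annulus that must be
#'   valid for the output cell to be defined (default 0.5).
#' @return a `moundr_grid` of focal means.
#' @export
focal_mean_annulus <- function(grid, annulus, min_valid_fraction = 0.5) {
  stopifnot_grid(grid)
  if (!inherits(annulus, "annulus_spec")) stop("`annulus` must be an annulus_spec")
  Z <- grid$values
  nr <- nrow(Z); nc <- ncol(Z)
  if (nr < 3L || nc < 3L) stop("grid must be at least 3x3")
  V <- !is.na(Z)
  if (!any(V)) stop("grid is entirely nodata")
  mu <- mean(Z[V])
  Zd <- Z - mu; Zd[!V] <- 0
  K <- annulus$outer
  P  <- matrix(0, nr + 2L * K, nc + 2L * K)
  Pv <- matrix(0, nr + 2L * K, nc + 2L * K)
  P [K + seq_len(nr), K + seq_len(nc)] <- Zd
  Pv[K + seq_len(nr), K + seq_len(nc)] <- as.numeric(V)
  runs <- annulus_runs(annulus)
  S <- matrix(0, nr, nc); N <- matrix(0, nr, nc)
  jj <- seq_len(nc)
  for (dy in -K:K) {
    rn <- runs[[dy + K + 1L]]
    if (is.null(rn)) next
    B  <- P [(K + dy) + seq_len(nr), , drop = FALSE]
    Bv <- Pv[(K + dy) + seq_len(nr), , drop = FALSE]
    CS  <- row_cumsum0(B)
    CSv <- row_cumsum0(Bv)
    for (k in seq_len(nrow(rn))) {
      a <- rn[k, 1]; b <- rn[k, 2]
      S <- S + CS [, jj + K + b + 1L, drop = FALSE] - CS [, jj + K + a, drop = FALSE]
      N <- N + CSv[, jj + K + b + 1L, drop = FALSE] - CSv[, jj + K + a, drop = FALSE]
    }
  }
  N <- round(N)
  k_total <- annulus_n_cells(annulus)
  ok <- N > 0 & (N / k_total) >= min_valid_fraction
  out <- matrix(NA_real_, nr, nc)
  out[ok] <- S[ok] / N[ok] + mu
  if (!any(ok)) warning("annulus exceeds grid extent: all-nodata focal mean")
  grid_like(grid, out)
}

# matrix shifted so that out[r, c] = m[r + dr, c + dc]; NA padding
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

#' Terrain slope (Horn 3x3 estimator)
#'
#' Slope in decimal degrees from the Horn (1981) third-order finite difference
#' over the 3x3 window, the estimator used by mainstream GIS packages. Cells
#' whose 3x3 window contains any nodata (including the grid border) are
#' nodata.
#'
#' @param grid a `moundr_grid` of elevations (metres, up-positive).
#' @return a `moundr_grid` of slope in degrees.
#' @export
slope <- function(grid) {
  stopifnot_grid(grid)
  z <- grid$values
  if (nrow(z) < 3L || ncol(z) < 3L) stop("grid must be at least 3x3")
  cs <- grid$cell_size
  a <- shift_mat(z, -1L, -1L); b <- shift_mat(z, -1L, 0L); cc <- shift_mat(z, -1L, 1L)
  d <- shift_mat(z,  0L, -1L);                              f  <- shift_mat(z,  0L, 1L)
  g <- shift_mat(z,  1L, -1L); h <- shift_mat(z,  1L, 0L); i  <- shift_mat(z,  1L, 1L)
  gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  gy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)
  s <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  s[is.na(z)] <- NA_real_
  grid_like(grid, s)
}

# focal 3x3 sum requiring all nine cells valid (NA otherwise)
focal_sum_3x3 <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dr in -1L:1L) for (dc in -1L:1L) out <- out + shift_mat(m, dr, dc)
  out
}

#' Terrain rugosity
#'
#' Two definitions of small-scale roughness over a 3x3 window:
#' `"sd_of_slope"` (the default used by the feature description step) is the
#' sample standard deviation of the Horn slope over the window;
#' `"surface_area_ratio"` is the Jenness (2004) eight-triangle estimate of the
#' 3D surface area divided by the planar cell area (1 on a horizontal plane).
#'
#' @param grid a `moundr_grid` of elevations.
#' @param method `"sd_of_slope"` or `"surface_area_ratio"`.
#' @return a `moundr_grid` of rugosity values.
#' @export
rugosity <- function(grid, method = c("sd_of_slope", "surface_area_ratio")) {
  stopifnot_grid(grid)
  method <- match.arg(method)
  if (method == "sd_of_slope") {
    s <- slope(grid)$values
    s1 <- focal_sum_3x3(s)
    s2 <- focal_sum_3x3(s^2)
    v <- pmax((s2 - s1^2 / 9) / 8, 0)   # sample variance, n = 9
    return(grid_like(grid, sqrt(v)))
  }
  z <- grid$values
  cs <- grid$cell_size
  # neighbours in ring order so consecutive entries are 45 degrees apart
  drs <- c(-1L, -1L, 0L, 1L, 1L,  1L,  0L, -1L)
  dcs <- c( 0L,  1L, 1L, 1L, 0L, -1L, -1L, -1L)
  planar <- cs * sqrt(1 + (drs != 0L & dcs != 0L))  # cs or cs*sqrt(2)
  zn <- lapply(seq_len(8L), function(k) shift_mat(z, drs[k], dcs[k]))
  half_leg <- lapply(seq_len(8L), function(k)
    sqrt(planar[k]^2 + (zn[[k]] - z)^2) / 2)
  area <- matrix(0, nrow(z), ncol(z))
  for (k in seq_len(8L)) {
    k2 <- if (k == 8L) 1L else k + 1L
    e <- sqrt(cs^2 + (zn[[k]] - zn[[k2]])^2) / 2   # neighbour centres are cs apart
    s <- (half_leg[[k]] + half_leg[[k2]] + e) / 2
    area <- area + sqrt(pmax(s * (s - half_leg[[k]]) *
                               (s - half_leg[[k2]]) * (s - e), 0))
  }
  grid_like(grid, area / cs^2)
}
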