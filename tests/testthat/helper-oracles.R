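# Independent brute-force oracles and fixture builders.

# focal annulus mean from first principles: enumerate the member offsets by
# a double loop over the kernel, then average them per cell
oracle_focal_mean <- function(z, inner, outer, min_valid_fraction = 0.5) {
  nr <- nrow(z); nc <- ncol(z)
  dys <- integer(0); dxs <- integer(0)
  for (dy in -outer:outer) for (dx in -outer:outer) {
    d <- sqrt(dx^2 + dy^2)
    if (d >= inner && d <= outer) { dys <- c(dys, dy); dxs <- c(dxs, dx) }
  }
  k_total <- length(dys)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- r + dys; cc <- c + dxs
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    v <- z[cbind(rr[ok], cc[ok])]
    v <- v[!is.na(v)]
    if (length(v) && length(v) / k_total >= min_valid_fraction)
      out[r, c] <- mean(v)
  }
  out
}

# Horn slope at a single interior cell, straight from the formula
oracle_horn_slope <- function(z, r, c, cs) {
  a <- z[r - 1, c - 1]; b <- z[r - 1, c]; cc <- z[r - 1, c + 1]
  d <- z[r, c - 1];                        f <- z[r, c + 1]
  g <- z[r + 1, c - 1]; h <- z[r + 1, c]; i <- z[r + 1, c + 1]
  gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  gy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)
  atan(sqrt(gx^2 + gy^2)) * 180 / pi
}

# 8-connected components by an explicit stack walk (independent of the
# package's frontier-expansion labelling)
oracle_regions <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (seed in which(mask)) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    stack <- seed
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[i] != 0L) next
      lab[i] <- cur
      r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
      for (dr in -1L:1L) for (dc in -1L:1L) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && lab[j] == 0L) stack <- c(stack, j)
      }
    }
  }
  lab
}

# even-odd point-in-polygon by the classic crossing loop
oracle_point_in_poly <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(px))
  for (k in seq_along(px)) {
    x <- px[k]; y <- py[k]; cross <- 0L
    for (i in seq_len(n)) {
      x1 <- ring[i, 1]; y1 <- ring[i, 2]
      x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
      if ((y1 > y) != (y2 > y)) {
        xi <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xi) cross <- cross + 1L
      }
    }
    inside[k] <- cross %% 2L == 1L
  }
  inside
}

# AUC as the fraction of concordant positive/negative pairs (ties half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# single anisotropic Gaussian mound DEM on a flat or sloping plane
mound_dem <- function(nr = 120L, nc = 120L, cs = 2, depth = -150,
                      height = 8, sd_short = 8, sd_long = 8, azimuth = 0,
                      slope_deg = 0, slope_azimuth = 180, seed = 1L,
                      noise_sd = 0, cx = nc * cs / 2, cy = nr * cs / 2) {
  sc <- scene_config(grid_shape = c(nr, nc), cell_size = cs, base_depth = depth,
                     plane_slope_deg = slope_deg, plane_azimuth_deg = slope_azimuth,
                     mounds = data.frame(x = cx, y = cy, height = height,
                                         sd_long = sd_long, sd_short = sd_short,
                                         azimuth = azimuth),
                     noise_sd = noise_sd, seed = seed)
  generate_dem(sc)
}

# wrap explicit cell sets (linear indices into `grid`) as a mound_features
# object, tracing rings with the package's tracer
features_from_cells <- function(grid, cellsets) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  feats <- lapply(seq_along(cellsets), function(i) {
    cells <- cellsets[[i]]
    ring <- moundr:::trace_outer_ring(cells, nr, nc, grid$cell_size,
                                      grid$xll, grid$yll)
    list(feature_id = i, cells = cells, raw_cells = cells,
         ring = ring, raw_ring = ring, merged_flag = FALSE, edited_flag = FALSE)
  })
  structure(list(features = feats,
                 grid = list(nrow = nr, ncol = nc, cell_size = grid$cell_size,
                             xll = grid$xll, yll = grid$yll, crs = grid$crs),
                 config = NULL),
            class = "mound_features")
}

# fabricated attribute table with independent predictors, for model tests
synthetic_attribute_table <- function(n, seed = 1L) {
  set.seed(seed)
  data.frame(
    feature_id = seq_len(n),
    MaxWD = runif(n, 120, 200),
    Max_Rug = runif(n, 0.5, 6),
    Mean_Rug = runif(n, 0.2, 3),
    Index = runif(n, 3, 9),
    MBG_Orient = runif(n, 0, 180),
    MaxCurrent = runif(n, 0.2, 0.8),
    Area = runif(n, 100, 4000),
    InitialSlp = runif(n, 0, 8))
}
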