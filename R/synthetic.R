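#' Synthetic seabed scene configuration
#'
#' Describes a simulated survey area with known ground truth: a sloping
#' plane at `base_depth`, an optional Gaussian ridge, a set of planted
#' anisotropic Gaussian mounds, seeded Gaussian measurement noise, a coarse
#' current raster, and a logistic label model that generates live-coral
#' presence from feature attributes. Scales follow the Mingulay mini-mound
#' setting: 2 m cells, mounds tens of metres across and a few metres high on
#' a ridge rising from ~200 m depth.
#'
#' @param grid_shape c(rows, cols) of the DEM.
#' @param cell_size metres per cell (default 2).
#' @param base_depth plane elevation at the grid centre (m, up-positive, so
#'   e.g. -180).
#' @param plane_slope_deg,plane_azimuth_deg regional slope (degrees) and its
#'   downhill azimuth (clockwise from north).
#' @param ridge optional list(height, sd, azimuth) adding a Gaussian ridge
#'   through the grid centre whose crest runs along `azimuth`.
#' @param mounds data.frame with columns `x`, `y` (centre coordinates),
#'   `height` (m), `sd_long`, `sd_short` (Gaussian sigmas, m), `azimuth`
#'   (degrees clockwise from north of the long axis). See
#'   [random_mound_field()].
#' @param noise_sd sd of iid Gaussian elevation noise (m).
#' @param seed integer seed for noise and labels.
#' @param label_model list(intercept, coef) where `coef` is a named vector of
#'   logistic coefficients applied to z-scored attribute columns.
#' @param coral_cover_rule target live-coral cover fraction on a present
#'   mound (default 0.3).
#' @param current_azimuth direction the residual current flows toward
#'   (degrees clockwise from north); coral discs are planted on the
#'   up-current flank.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(grid_shape = c(200L, 200L), cell_size = 2,
                         base_depth = -180, plane_slope_deg = 1,
                         plane_azimuth_deg = 180, ridge = NULL,
                         mounds = NULL, noise_sd = 0, seed = 1L,
                         label_model = list(
                           intercept = 0,
                           coef = c(MaxWD = 1.5, Max_Rug = 1, Index = 1,
                                    MaxCurrent = -0.5)),
                         coral_cover_rule = 0.3,
                         current_azimuth = 45) {
  if (is.null(mounds))
    mounds <- data.frame(x = numeric(0), y = numeric(0), height = numeric(0),
                         sd_long = numeric(0), sd_short = numeric(0),
                         azimuth = numeric(0))
  stopifnot(all(c("x", "y", "height", "sd_long", "sd_short", "azimuth") %in%
                  names(mounds)))
  if (nrow(mounds) && any(mounds$height <= 0)) stop("mound heights must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ext <- c(grid_shape[2], grid_shape[1]) * cell_size
  if (nrow(mounds) &&
      any(mounds$x < 0 | mounds$x > ext[1] | mounds$y < 0 | mounds$y > ext[2]))
    stop("mound centres must lie inside the grid")
  structure(list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
                 base_depth = base_depth, plane_slope_deg = plane_slope_deg,
                 plane_azimuth_deg = plane_azimuth_deg, ridge = ridge,
                 mounds = mounds, noise_sd = noise_sd, seed = as.integer(seed),
                 label_model = label_model,
                 coral_cover_rule = coral_cover_rule,
                 current_azimuth = current_azimuth),
            class = "scene_config")
}

#' Random planted-mound field
#'
#' Draws `n` mounds on a jittered grid with dimensions in the range reported
#' for the Mingulay mini-mounds (footprints roughly 15-60 m wide and up to
#' ~80 m long, heights 4.5-9 m), guaranteeing centres stay `margin` metres
#' away from the DEM edge so the delineation annulus has full support.
#'
#' @param n number of mounds.
#' @param extent c(width, height) of the area in metres.
#' @param seed integer seed.
#' @param margin edge clearance in metres (default 80).
#' @return a `mounds` data.frame for [scene_config()].
#' @export
random_mound_field <- function(n, extent, seed = 1L, margin = 80) {
  set.seed(seed)
  usable <- extent - 2 * margin
  if (any(usable <= 0)) stop("extent too small for the requested margin")
  ncol_g <- max(1L, round(sqrt(n * usable[1] / usable[2])))
  nrow_g <- ceiling(n / ncol_g)
  gx <- (seq_len(ncol_g) - 0.5) / ncol_g * usable[1] + margin
  gy <- (seq_len(nrow_g) - 0.5) / nrow_g * usable[2] + margin
  pts <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  jx <- min(diff(c(0, gx))[1], 60) / 4
  sd_short <- stats::runif(n, 3.5, 9)
  data.frame(
    x = pts$x + stats::runif(n, -jx, jx),
    y = pts$y + stats::runif(n, -jx, jx),
    height = stats::runif(n, 4.5, 9),
    sd_short = sd_short,
    sd_long = pmin(16, sd_short / stats::runif(n, 0.4, 1)),
    azimuth = stats::runif(n, 0, 180))
}

#' The 120-mound reference scene
#'
#' The package's standard synthetic study area: 700 x 1000 cells at 2 m
#' (1.4 x 2 km), a 1-degree south-dipping plane at 180 m depth, and 120
#' planted Gaussian mounds at the published mini-mound scale.
#'
#' @param n_mounds number of planted mounds (default 120).
#' @param noise_sd elevation noise sd in metres (default 0, the noise-free
#'   reference).
#' @param seed integer seed.
#' @param grid_shape c(rows, cols); default c(700, 1000).
#' @return a [scene_config()].
#' @export
reference_scene_config <- function(n_mounds = 120L, noise_sd = 0, seed = 42L,
                                   grid_shape = c(700L, 1000L)) {
  ext <- c(grid_shape[2], grid_shape[1]) * 2
  scene_config(grid_shape = grid_shape, cell_size = 2, base_depth = -180,
               plane_slope_deg = 1, plane_azimuth_deg = 180,
               mounds = random_mound_field(n_mounds, ext, seed = seed),
               noise_sd = noise_sd, seed = seed)
}

# mound elevation term of mound m over coordinate vectors x, y
mound_term <- function(m, x, y) {
  az <- m$azimuth * pi / 180
  u <- (x - m$x) * sin(az) + (y - m$y) * cos(az)   # along long axis
  v <- (x - m$x) * cos(az) - (y - m$y) * sin(az)
  m$height * exp(-(u^2 / (2 * m$sd_long^2) + v^2 / (2 * m$sd_short^2)))
}

#' Generate the synthetic DEM and ground-truth registry
#'
#' Builds `DEM = plane + ridge + sum of mounds + noise` and records, per
#' mound, its planted parameters and footprint (the cells where the mound
#' term reaches at least 0.2 m). Overlapping footprints are allowed but
#' flagged. Seeded runs are bit-identical.
#'
#' @param config a [scene_config()].
#' @return list with `dem` (a `moundr_grid`) and `registry` (data.frame with
#'   the planted parameters, `footprint` as a list-column of linear cell
#'   indices, and `overlaps`).
#' @export
generate_dem <- function(config) {
  if (!inherits(config, "scene_config")) stop("`config` must be a scene_config")
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  cs <- config$cell_size
  xc <- (seq_len(nc) - 0.5) * cs
  yc <- (nr - seq_len(nr) + 0.5) * cs
  X <- matrix(xc, nr, nc, byrow = TRUE)
  Y <- matrix(yc, nr, nc)
  azp <- config$plane_azimuth_deg * pi / 180
  grad <- tan(config$plane_slope_deg * pi / 180)
  z <- config$base_depth -
    grad * ((X - mean(xc)) * sin(azp) + (Y - mean(yc)) * cos(azp))
  if (!is.null(config$ridge)) {
    azr <- config$ridge$azimuth * pi / 180
    d <- (X - mean(xc)) * cos(azr) - (Y - mean(yc)) * sin(azr)
    z <- z + config$ridge$height * exp(-d^2 / (2 * config$ridge$sd^2))
  }
  mounds <- config$mounds
  footprints <- vector("list", nrow(mounds))
  if (nrow(mounds)) for (i in seq_len(nrow(mounds))) {
    m <- mounds[i, ]
    reach <- 4 * max(m$sd_long, m$sd_short)
    c0 <- max(1L, floor((m$x - reach) / cs)); c1 <- min(nc, ceiling((m$x + reach) / cs))
    r0 <- max(1L, nr - ceiling((m$y + reach) / cs) + 1L)
    r1 <- min(nr, nr - floor((m$y - reach) / cs))
    rs <- r0:r1; csel <- c0:c1
    term <- mound_term(m, X[rs, csel, drop = FALSE], Y[rs, csel, drop = FALSE])
    z[rs, csel] <- z[rs, csel] + term
    fp <- which(term >= 0.2, arr.ind = TRUE)
    footprints[[i]] <- (csel[fp[, 2]] - 1L) * nr + rs[fp[, 1]]
  }
  if (config$noise_sd > 0) {
    set.seed(config$seed)
    z <- z + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  }
  overlaps <- logical(nrow(mounds))
  if (nrow(mounds) > 1L) {
    all_fp <- unlist(footprints)
    dup <- unique(all_fp[duplicated(all_fp)])
    overlaps <- vapply(footprints, function(f) any(f %in% dup), logical(1))
  }
  registry <- cbind(mound_id = seq_len(nrow(mounds)), mounds,
                    overlaps = overlaps)
  registry$footprint <- footprints
  list(dem = grid_create(z, cs, 0, 0, "synthetic"), registry = registry)
}

#' Coarse synthetic current raster
#'
#' A smooth current-speed field at `cell_size` resolution (default 100 m,
#' mirroring the hydrodynamic-model grid): a base speed plus a linear
#' west-east gradient.
#'
#' @param extent c(width, height) of the area in metres.
#' @param cell_size metres per cell (default 100).
#' @param base,gradient base speed (m/s) and its increase per km eastward.
#' @return a `moundr_grid`.
#' @export
generate_current <- function(extent, cell_size = 100, base = 0.3,
                             gradient = 0.1) {
  nc <- max(1L, ceiling(extent[1] / cell_size))
  nr <- max(1L, ceiling(extent[2] / cell_size))
  x <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - 0.5) * cell_size
  grid_create(base + gradient * x / 1000, cell_size, 0, 0, "synthetic")
}

#' Generate presence labels and coral-cover polygons
#'
#' Presence is drawn Bernoulli with probability
#' `plogis(intercept + sum(coef * zscore(attribute)))` using the label-model
#' coefficients of the scene config (applied to the named attribute columns,
#' z-scored across features). For each present feature a disc of live-coral
#' cover totalling `coral_cover_rule` of the feature area is planted on its
#' up-current flank.
#'
#' @param attributes data.frame from [describe_features()] (plus `MaxCurrent`
#'   if the label model uses it).
#' @param config the [scene_config()] that generated the scene.
#' @return list with `labels` (data.frame: `feature_id`, `presence_prob`,
#'   `presence`) and `coral_polygons` (list of closed rings, possibly empty).
#' @export
generate_labels <- function(attributes, config) {
  if (!inherits(config, "scene_config")) stop("`config` must be a scene_config")
  if (!nrow(attributes))
    return(list(labels = data.frame(feature_id = integer(0),
                                    presence_prob = numeric(0),
                                    presence = integer(0)),
                coral_polygons = list()))
  lm <- config$label_model
  lin <- rep(lm$intercept, nrow(attributes))
  for (nm in names(lm$coef)) {
    if (!nm %in% names(attributes)) next
    v <- attributes[[nm]]
    s <- stats::sd(v, na.rm = TRUE)
    zv <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v, na.rm = TRUE)) / s
    zv[is.na(zv)] <- 0
    lin <- lin + lm$coef[[nm]] * zv
  }
  prob <- stats::plogis(lin)
  set.seed(config$seed + 1L)
  presence <- stats::rbinom(length(prob), 1L, prob)
  # coral discs on the up-current flank of present features
  up <- (config$current_azimuth + 180) * pi / 180
  polys <- list()
  theta <- seq(0, 2 * pi, length.out = 65L)
  for (i in which(presence == 1L)) {
    a <- attributes[i, ]
    if (is.na(a$Area) || a$Area <= 0) next
    rad <- sqrt(config$coral_cover_rule * a$Area / pi)
    cx <- a$centroid_x + 0.5 * rad * sin(up)
    cy <- a$centroid_y + 0.5 * rad * cos(up)
    polys[[length(polys) + 1L]] <-
      cbind(x = cx + rad * cos(theta), y = cy + rad * sin(theta))
  }
  list(labels = data.frame(feature_id = attributes$feature_id,
                           presence_prob = prob, presence = presence),
       coral_polygons = polys)
}

#' Score planted-mound recovery
#'
#' A delineated feature is attributed to a planted mound when at least half
#' of the feature's cells fall inside the mound's planted footprint (the
#' cells where the mound term reaches 0.2 m; the BPI-thresholded outline is
#' necessarily a subset of this wider footprint). A mound counts as recovered
#' one-to-one when exactly one feature is attributed to it; a feature
#' attributed to no mound is spurious.
#'
#' @param registry registry from [generate_dem()].
#' @param features a `mound_features` from [delineate()].
#' @return list with `n_mounds`, `n_features`, `recovered` (logical per
#'   mound), `recovery_rate`, `one_to_one` (recovered by exactly one
#'   feature), `n_spurious`.
#' @export
score_recovery <- function(registry, features) {
  n_m <- nrow(registry)
  n_f <- length(features$features)
  covers <- matrix(FALSE, n_m, max(1L, n_f))
  for (i in seq_len(n_m)) {
    fp <- registry$footprint[[i]]
    for (j in seq_len(n_f)) {
      fc <- features$features[[j]]$cells
      covers[i, j] <- sum(fc %in% fp) >= 0.5 * length(fc)
    }
  }
  n_cover <- rowSums(covers)
  recovered <- n_cover >= 1L
  one_to_one <- n_cover == 1L
  assigned <- if (n_f) colSums(covers[, seq_len(n_f), drop = FALSE]) > 0 else logical(0)
  list(n_mounds = n_m, n_features = n_f, recovered = recovered,
       recovery_rate = mean(recovered), one_to_one = one_to_one,
       n_spurious = sum(!assigned))
}
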