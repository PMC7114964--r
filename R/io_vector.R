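#' Write features (with attributes) to GeoJSON
#'
#' Serialises the buffered outlines as a GeoJSON FeatureCollection in the
#' grid's projected coordinates, with any attribute columns attached as
#' properties (matched by `feature_id`).
#'
#' @param features a `mound_features` object.
#' @param path output `.geojson` path.
#' @param attributes optional data.frame with a `feature_id` column.
#' @return `path`, invisibly.
#' @export
write_features_geojson <- function(features, path, attributes = NULL) {
  if (!inherits(features, "mound_features"))
    stop("`features` must be a mound_features object")
  feats <- lapply(features$features, function(f) {
    props <- list(feature_id = f$feature_id, merged_flag = f$merged_flag,
                  edited_flag = f$edited_flag)
    if (!is.null(attributes)) {
      row <- attributes[attributes$feature_id == f$feature_id, , drop = FALSE]
      if (nrow(row) == 1L)
        props <- c(props, lapply(row[setdiff(names(row), "feature_id")],
                                 function(v) unname(v)))
    }
    coords <- lapply(seq_len(nrow(f$ring)), function(i) unname(f$ring[i, ]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  obj <- list(type = "FeatureCollection",
              crs_tag = features$grid$crs, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' Reads the outer rings of all Polygon/MultiPolygon features of a GeoJSON
#' file into a list of closed two-column matrices (the format consumed by
#' [cover_class()]).
#'
#' @param path a `.geojson` file.
#' @return list of closed rings.
#' @export
read_polygons_geojson <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path)
  feats <- if (identical(obj$type, "FeatureCollection")) obj$features
           else list(obj)
  rings <- list()
  add_ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("x", "y")
    rings[[length(rings) + 1L]] <<- close_ring(m)
  }
  for (f in feats) {
    g <- if (identical(f$type, "Feature")) f$geometry else f
    if (is.null(g)) next
    if (identical(g$type, "Polygon")) add_ring(g$coordinates[[1]])
    else if (identical(g$type, "MultiPolygon"))
      for (poly in g$coordinates) add_ring(poly[[1]])
  }
  rings
}

#' Render the per-feature prediction map
#'
#' Draws the delineated outlines coloured by predicted presence probability
#' (light = likely absent, dark = likely present) on a depth-shaded
#' background, optionally to a PNG file.
#'
#' @param features a `mound_features` object.
#' @param predictions data.frame from [predict_map()] with `feature_id` and
#'   `presence_prob`.
#' @param dem optional background `moundr_grid`.
#' @param file optional PNG path; when `NULL` draws on the active device.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_prediction_map <- function(features, predictions, dem = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 900, res = 130)
    on.exit(grDevices::dev.off())
  }
  geo <- features$grid
  xlim <- c(geo$xll, geo$xll + geo$ncol * geo$cell_size)
  ylim <- c(geo$yll, geo$yll + geo$nrow * geo$cell_size)
  graphics::plot(NA, xlim = xlim, ylim = ylim, asp = 1,
                 xlab = "Easting (m)", ylab = "Northing (m)",
                 main = "Likelihood of live coral presence")
  if (!is.null(dem)) {
    z <- dem$values[nrow(dem$values):1, , drop = FALSE]
    graphics::image(x = seq(xlim[1], xlim[2], length.out = ncol(z)),
                    y = seq(ylim[1], ylim[2], length.out = nrow(z)),
                    z = t(z), col = grDevices::gray.colors(64), add = TRUE)
  }
  pal <- grDevices::colorRampPalette(c("#fee8c8", "#7f0000"))(101)
  for (f in features$features) {
    p <- predictions$presence_prob[match(f$feature_id, predictions$feature_id)]
    col <- if (is.na(p)) "grey70" else pal[round(p * 100) + 1L]
    graphics::polygon(f$ring[, 1], f$ring[, 2], col = col, border = "grey30")
  }
  invisible(file)
}
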