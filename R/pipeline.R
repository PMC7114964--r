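#' Run the full mapping-and-modelling pipeline
#'
#' Chains the stages end-to-end from a single configuration: BPI computation,
#' feature delineation, attribute description, current join and coral-cover
#' classification, random-forest training, and the per-feature predictive
#' map. The configuration is a YAML file (or an equivalent list) with the
#' blocks below; every threshold actually applied is echoed into a run
#' manifest (`manifest.json`) together with per-stage counts and output-file
#' checksums, which suffices to reproduce the run.
#'
#' ```yaml
#' scene:               # EITHER a synthetic scene ...
#'   n_mounds: 40
#'   noise_sd: 0.3
#'   seed: 7
#'   grid_shape: [300, 400]
#' dem: dem.asc         # ... OR input rasters (ESRI ASCII)
#' backscatter: bs.asc  # optional
#' current: cur.asc     # optional
#' coral: coral.geojson # optional live-coral polygon layer
#' bpi: {inner: 8, outer: 24}
#' delineation: {cutline_bpi: 3, min_bpi: 3.5, min_area: 50,
#'               min_wl_ratio: 0.2, buffer_distance: 4}
#' description: {contour_interval: 0.5}
#' model: {n_trees: 1500, vars_per_split: 6, seed: 1}
#' ```
#'
#' @param config path to a YAML config, or a list with the same structure.
#' @param out_dir output directory (created if absent).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file or a list")
  if (is.null(config$scene) && is.null(config$dem))
    stop("config schema violation: need either field `scene` or field `dem`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("moundr")),
    r_version = R.version.string,
    config = config, stages = list(), outputs = list())

  scene <- NULL
  registry <- NULL
  if (!is.null(config$scene)) {
    sc <- config$scene
    scene <- reference_scene_config(
      n_mounds = sc$n_mounds %||% 120L,
      noise_sd = sc$noise_sd %||% 0,
      seed = sc$seed %||% 42L,
      grid_shape = as.integer(unlist(sc$grid_shape %||% c(700L, 1000L))))
    gen <- generate_dem(scene)
    dem <- gen$dem
    registry <- gen$registry
    current <- generate_current(
      c(scene$grid_shape[2], scene$grid_shape[1]) * scene$cell_size)
    backscatter <- NULL
    write_raster(dem, file.path(out_dir, "dem.asc"))
    write_raster(current, file.path(out_dir, "current.asc"))
    manifest$stages$scene <- list(n_mounds = nrow(registry),
                                  noise_sd = scene$noise_sd,
                                  seed = scene$seed)
  } else {
    dem <- read_raster(config$dem, depth_positive = isTRUE(config$depth_positive))
    current <- if (!is.null(config$current)) read_raster(config$current) else NULL
    backscatter <- if (!is.null(config$backscatter))
      read_raster(config$backscatter) else NULL
  }

  ann <- annulus_spec(config$bpi$inner %||% 8L, config$bpi$outer %||% 24L)
  bpi <- compute_bpi(dem, ann)
  write_raster(bpi, file.path(out_dir, "bpi.asc"))
  manifest$stages$bpi <- list(inner = ann$inner, outer = ann$outer)

  dcfg <- do.call(delineation_config, config$delineation %||% list())
  features <- delineate(bpi, dcfg)
  manifest$stages$delineation <- c(unclass(dcfg),
                                   list(n_features = length(features$features)))
  if (!length(features$features)) {
    warning("no features delineated; stopping after delineation")
    path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(manifest))
  }

  rug <- rugosity(dem)
  ci <- (config$description %||% list())$contour_interval %||% 0.5
  attrs <- describe_features(dem, bpi, features, rug, backscatter,
                             contour_interval = ci)
  if (!is.null(current)) attrs <- join_current(attrs, current)
  manifest$stages$description <- list(n_records = nrow(attrs),
                                      contour_interval = ci)

  coral <- NULL
  if (!is.null(scene)) {
    lab <- generate_labels(attrs, scene)
    coral <- lab$coral_polygons
    manifest$stages$labels <- list(n_present = sum(lab$labels$presence))
  } else if (!is.null(config$coral)) {
    coral <- read_polygons_geojson(config$coral)
  }
  if (!is.null(coral) && length(coral)) {
    cov <- cover_class(features, coral)
    attrs <- merge(attrs, cov, by = "feature_id", sort = TRUE)
    manifest$stages$cover <- as.list(table(cov$CoverClass))
  } else if (!is.null(coral)) {
    attrs$CoverPct <- 0; attrs$CoverClass <- "=0"; attrs$presence <- FALSE
  }
  utils::write.csv(attrs, file.path(out_dir, "attributes.csv"),
                   row.names = FALSE)
  write_features_geojson(features, file.path(out_dir, "mounds.geojson"), attrs)

  if (!is.null(attrs$presence) && length(unique(attrs$presence)) == 2L) {
    mcfg_in <- config$model %||% list()
    mcfg <- model_config(n_trees = mcfg_in$n_trees %||% 1500L,
                         vars_per_split = mcfg_in$vars_per_split %||% 6L,
                         test_fraction = mcfg_in$test_fraction %||% 1 / 3,
                         correlation_cutoff = mcfg_in$correlation_cutoff %||% 0.95,
                         seed = mcfg_in$seed %||% 1L)
    y <- factor(as.integer(attrs$presence), levels = c(0L, 1L))
    preds <- select_predictors(attrs, y, mcfg)
    fit <- train_rf(attrs, y, preds, mcfg)
    pm <- predict_map(fit, attrs)
    utils::write.csv(pm, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(predictor = names(fit$report$importance),
                 mean_decrease_accuracy = unname(fit$report$importance)),
      file.path(out_dir, "importance.csv"), row.names = FALSE)
    rc <- response_curves(fit, attrs)
    rc_df <- do.call(rbind, lapply(names(rc), function(nm)
      cbind(predictor = nm, rc[[nm]])))
    utils::write.csv(rc_df, file.path(out_dir, "response_curves.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(predictors = fit$predictors,
           oob_error = fit$report$oob_error,
           oob_class_errors = as.list(fit$report$oob_class_errors),
           holdout = fit$report$holdout,
           importance = as.list(fit$report$importance)),
      file.path(out_dir, "model_report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
    plot_prediction_map(features, pm, dem,
                        file = file.path(out_dir, "prediction_map.png"))
    manifest$stages$model <- list(predictors = preds,
                                  n_trees = mcfg$n_trees,
                                  vars_per_split = mcfg$vars_per_split,
                                  seed = mcfg$seed,
                                  oob_error = fit$report$oob_error,
                                  holdout = fit$report$holdout[
                                    intersect(names(fit$report$holdout),
                                              c("sensitivity", "specificity",
                                                "auc", "n"))])
  }

  outs <- list.files(out_dir, full.names = TRUE)
  outs <- outs[basename(outs) != "manifest.json"]
  manifest$outputs <- as.list(tools::md5sum(outs))
  names(manifest$outputs) <- basename(outs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
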