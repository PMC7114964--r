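# moundr

Semi-automatic delineation of seabed coral mounds from multibeam
bathymetry, and random-forest prediction of live cold-water coral
presence.

Small positive-relief reef mounds ("mini-mounds", tens of metres across
and a few metres high) are a key habitat of framework-building cold-water
corals. `moundr` re-implements a survey workflow for mapping them from a
bathymetry grid:

* **BPI** — the bathymetric positioning index: per-cell elevation minus
  the mean elevation over an annular neighbourhood (default inner radius
  8, outer 24 cells; inclusive Euclidean membership), so mound tops stand
  out as positive values in metres.
* **Delineation** — BPI thresholding (cutline 3 m), 8-connected region
  growing, filters on maximum BPI (≥ 3.5 m), area (≥ 50 m²) and
  bounding-rectangle width/length (≥ 0.2), polygonisation and a 4 m
  outward buffer. Touching outlines are flagged, never dissolved.
* **Description** — per-feature attribute records: area, perimeter, BPI
  index, minimum-bounding-rectangle shape and orientation, water depths,
  deepest confined contour (`ConfCL_WD`), vertical relief, rugosity,
  backscatter, reconstructed pre-mound slope by harmonic infill
  (`InitialSlp`), joined current speed, and five-class live-coral cover
  from mapped polygons.
* **Habitat model** — `randomForest` (1500 trees, 6 variables per split,
  stratified 2/3–1/3 holdout) with collinearity-aware predictor
  selection, permutation importance, partial-dependence response curves,
  confusion-matrix / sensitivity / specificity / AUC evaluation, and a
  per-feature predictive map.
* **Synthetic scenes** — planted Gaussian-mound DEMs with full ground
  truth (registry, footprints, logistic presence labels, coral-cover
  discs, coarse current field) so the entire pipeline is testable
  offline.

Everything runs on plain R matrices: raster I/O is ESRI ASCII grid,
vector output is GeoJSON. See the methods vignette
(`vignettes/moundr-methods.Rmd`) for algorithms, parameter meanings and
known limitations.

## Worked example

Simulate a small survey, map the mounds, and describe them:

```r
library(moundr)

# a synthetic survey: 6 planted mounds on a 360 x 300 m sloping seabed
scene <- reference_scene_config(n_mounds = 6L, noise_sd = 0.2, seed = 5L,
                                grid_shape = c(150L, 180L))
gen <- generate_dem(scene)
gen$dem
#> <moundr_grid> 150 rows x 180 cols @ 2 m
#>   lower-left corner: (0, 0)  crs: synthetic
#>   values: [-183.114, -171.946], 0 nodata cells

bpi <- compute_bpi(gen$dem, annulus_spec(8L, 24L))
feats <- delineate(bpi, delineation_config())
feats
#> <mound_features> 6 features (cell size 2 m)

attrs <- describe_features(gen$dem, bpi, feats)
attrs <- join_current(attrs, generate_current(c(360, 300)))
round(attrs[1:3, c("feature_id", "Area", "Index", "MBG_W_L", "MaxWD",
                   "ConfCL_WD", "MaxVRelief", "Mean_Rug", "InitialSlp",
                   "MaxCurrent")], 3)
#>   feature_id Area Index MBG_W_L   MaxWD ConfCL_WD MaxVRelief Mean_Rug
#> 1          1  324 7.577   0.933 178.957     177.5      7.011    7.117
#> 2          2  484 7.144   0.625 180.356     178.5      6.812    5.986
#> 3          3  320 5.500   1.000 178.948     177.0      5.048    6.225
#>   InitialSlp MaxCurrent
#> 1      2.609      0.315
#> 2      3.242      0.315
#> 3      4.510      0.315

# ground truth says every planted mound was found exactly once
sc <- score_recovery(gen$registry, feats)
sprintf("recovered %d/%d planted mounds one-to-one, %d spurious",
        sum(sc$one_to_one), sc$n_mounds, sc$n_spurious)
#> [1] "recovered 6/6 planted mounds one-to-one, 0 spurious"

# live-coral cover classes from the scene's planted coral polygons
lab <- generate_labels(attrs, scene)
cov <- cover_class(feats, lab$coral_polygons)
table(cov$CoverClass)
#> ]25;50]      =0
#>       4       2
```

Fit the presence model on a larger attribute table:

```r
set.seed(42)
n <- 200
attrs <- data.frame(feature_id = seq_len(n),
                    MaxWD = runif(n, 120, 200), Max_Rug = runif(n, 0.5, 6),
                    Mean_Rug = runif(n, 0.2, 3), Index = runif(n, 3, 9),
                    MBG_Orient = runif(n, 0, 180),
                    MaxCurrent = runif(n, 0.2, 0.8),
                    Area = runif(n, 100, 4000), InitialSlp = runif(n, 0, 8))
zs <- function(v) (v - mean(v)) / sd(v)
presence <- factor(rbinom(n, 1, plogis(1.5 * zs(attrs$MaxWD) +
                                       zs(attrs$Max_Rug) + zs(attrs$Index))),
                   levels = 0:1)
preds <- select_predictors(attrs, presence, model_config())
fit <- train_rf(attrs, presence, preds, model_config(seed = 1L))
fit
#> <mound_rf> 1500 trees, mtry 6, 8 predictors
#>   training OOB error: 0.3459
#>   holdout: sensitivity 0.781, specificity 0.771, AUC 0.861
round(fit$report$importance[1:4], 2)
#>   MaxWD Max_Rug   Index    Area
#>   28.32   17.93   11.31    1.45
```

The whole chain — scene (or DEM on disk), BPI, delineation, description,
cover, model, predictive map, run manifest — is also available as one
call, `run_pipeline(config, out_dir)`, driven by a YAML config, and as a
command-line script (`inst/cli/moundr`).

## Running the tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "moundr",
                               load_package = "installed")'
```

The suite includes acceptance tests that reproduce the published
confusion-matrix error rates exactly, verify BPI against a brute-force
oracle to 1e-9, check analytic terrain limits, and demonstrate
planted-mound recovery on a 120-mound reference scene (all mounds
recovered one-to-one with zero spurious detections, noise-free and at
0.3 m noise).

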