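---
title: "Methods: mound delineation, description and coral habitat modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mound delineation, description and coral habitat modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moundr)
```

## Scope and model

`moundr` maps small positive-relief seabed features ("mini-mounds", tens of
metres across and a few metres high) from gridded multibeam bathymetry and
models the likelihood that each feature carries live cold-water coral
framework. The workflow has five stages:

1. **BPI** — the bathymetric positioning index, per cell: elevation minus
   the mean elevation over an annular neighbourhood. Positive BPI marks
   locally shallow terrain (mound tops), negative BPI locally deep terrain.
2. **Delineation** — threshold the BPI raster, group cells into candidate
   regions, filter them by relief, area and shape, and trace polygons.
3. **Description** — compute a standard attribute record per feature
   (depths, relief, bounding-rectangle shape, rugosity, backscatter,
   reconstructed pre-mound slope), join coarse current-speed data, and
   classify live-coral cover from mapped polygons.
4. **Habitat model** — a random-forest classifier of coral presence (or
   five-class cover) over the attribute records, with permutation
   importance, partial-dependence response curves and confusion/ROC
   evaluation.
5. **Prediction** — per-feature presence probability as the forest vote
   fraction, rendered as a predictive map.

All elevation grids are stored up-positive (seabed depths negative);
reported water depths (`MinWD` etc.) are positive-down metres.

## BPI and its parameters

A cell at offset $(dx, dy)$ (in cells) belongs to the annulus when its
centre-to-centre Euclidean distance satisfies
$\mathrm{inner} \le \sqrt{dx^2 + dy^2} \le \mathrm{outer}$, bounds
inclusive. The defaults are **inner 8, outer 24 cells** — at the 2 m grid
of the motivating survey, a 16–48 m ring sized to the mound footprints, so
a mound summit is compared against the surrounding seabed rather than its
own flanks. BPI is kept in raw metres (no standardisation): the delineation
thresholds below are metre-scaled.

```{r bpi-demo}
gen <- generate_dem(reference_scene_config(n_mounds = 6L, seed = 5L,
                                           grid_shape = c(150L, 180L)))
bpi <- compute_bpi(gen$dem, annulus_spec(8L, 24L))
bpi
```

Cells whose valid-neighbour fraction falls below `min_valid_fraction`
(default 0.5, i.e. near the grid edge or large nodata patches) become
nodata rather than being estimated from a biased partial ring.

**Numerical design.** The focal mean is computed exactly (not by FFT
convolution) by decomposing the annulus into per-row runs of member
offsets and accumulating row cumulative sums, which is $O(\text{rows}
\times \text{cols} \times \text{kernel rows})$ and bit-stable. The grid is
globally demeaned before accumulation and the mean added back, so BPI is
invariant under adding a constant to all depths to within 1e-9 — verified
against a brute-force double loop in the test suite. Counts are
accumulated the same way and rounded to exact integers.

## Terrain derivatives

* **Slope** — Horn's (1981) third-order finite difference over the 3×3
  window, in decimal degrees; the estimator used by mainstream GIS. Cells
  with any nodata neighbour are nodata.
* **Rugosity** — two definitions: `"sd_of_slope"` (default; the sample
  standard deviation of slope over the 3×3 window, in degrees) and
  `"surface_area_ratio"` (Jenness' eight-triangle 3D/planar area ratio, 1
  on a horizontal plane). On a constant-slope plane the sd-of-slope is
  zero up to ~1e-8 — the square root of the floating-point cancellation in
  the variance — which the tests treat as the attainable zero.

## Delineation

`delineate()` applies, in order (defaults in parentheses, from the
motivating survey):

1. threshold: cells with BPI ≥ `cutline_bpi` (**3 m**);
2. 8-connected region growing, regions numbered by their smallest
   column-major cell index (deterministic ordering);
3. filters on the *raw* regions: maximum BPI ≥ `min_bpi` (**3.5 m**),
   area ≥ `min_area` (**50 m²**), minimum-bounding-rectangle
   width/length ≥ `min_wl_ratio` (**0.2**);
4. polygonisation along cell boundaries (outer ring, counterclockwise);
5. outward buffering by `buffer_distance` (**4 m**), implemented as
   Euclidean dilation on the grid. Buffering is cosmetic: it never
   changes which regions survive. Buffered outlines that touch a
   neighbour are flagged (`merged_flag`) but never dissolved, mirroring
   the manual-editing step of the original workflow.

Buffering by grid dilation (rather than exact round-joined polygon
offsetting) keeps every downstream computation on the raster and is exact
to within half a cell; with `buffer_distance = 0` the buffered ring is
identical to the raw ring.

```{r delineate-demo}
feats <- delineate(bpi, delineation_config())
feats
```

## Feature description

`describe_features()` emits one record per feature with the standard
attribute set: polygon `Area` and `Perimeter`; `Index` (maximum BPI);
bounding-rectangle `MBG_Width`, `MBG_Length`, `MBG_W_L` and `MBG_Orient`
(azimuth of the long axis, clockwise from north in [0, 180), 0 on a
square tie); `MinWD`/`MeanWD`/`MaxWD`; `ConfCL_WD`; `MinVRelief` and
`MaxVRelief`; rugosity and backscatter zonal statistics; and
`InitialSlp`. Zonal statistics run over the buffered outline's cells.

* **ConfCL_WD** — the depth of the deepest closed contour confined
  entirely inside the outline: contour levels at multiples of
  `contour_interval` (default **0.5 m**) descend from the summit; at each
  level the 8-connected component of cells above the level containing the
  summit is flood-filled, and the descent stops at the first level that
  escapes the outline. `MinVRelief = ConfCL_WD − MinWD` (relief of the
  summit above that contour), `MaxVRelief = MaxWD − MinWD`.
* **InitialSlp** — the reconstructed pre-mound slope: the feature's cells
  are voided and refilled by harmonic (Laplace) interpolation with the
  surrounding ring as boundary, solving the 5-point sparse linear system
  with a direct solver (`Matrix::solve`); the attribute is the mean Horn
  slope of the reconstruction over the voided cells. Harmonic infill
  reproduces planes exactly, so a mound planted on a 5° plane yields
  5.00° (tested to 0.5°). Features touching the raster edge or bordered
  by nodata raise an informative error and get `NA`.
* **MaxCurrent** — joined from a coarse current raster (typically 100 m
  cells) by centroid lookup, mirroring a GIS attribute join.
* **Cover** — live-coral polygons are overlaid by dense point sampling
  (5×5 points per 2 m cell, even-odd rule, union across polygons), and
  percent cover is binned into the five classes `=0`, `]0;25]`,
  `]25;50]`, `]50;75]`, `]75;100]` (left-exclusive, right-inclusive).

## Habitat model

`train_rf()` fits a `randomForest` classifier with the published settings:
**1500 trees**, **6 variables per split** (capped at the predictor count),
a stratified 2/3–1/3 train/holdout split, and permutation importance
(mean decrease in accuracy). `select_predictors()` first drops constant
columns and collapses collinear groups (pairwise $r^2 >$ 0.95,
transitively) keeping the member best explaining the response — the
treatment that left only maximum water depth from the four correlated
depth variables in the original analysis. Out-of-bag statistics are
reported on the training partition; sensitivity, specificity and a
rank-statistic (Mann–Whitney, ties half) AUC on the holdout. Fixing the
seed fixes the split, the forest and every reported number.
`response_curves()` computes probability-scale partial dependence on a
25-point grid; `predict_map()` scores every feature with the forest vote
fraction.

## Synthetic scenes and ground truth

Because the original multibeam, video and hydrodynamic data are not
redistributable, the package ships a generator producing scenes at the
same scales: a sloping plane (default 1° at 180 m depth), an optional
Gaussian ridge, planted anisotropic Gaussian mounds (heights 4.5–9 m,
short-axis sigma 3.5–9 m, long axis up to 16 m — footprints roughly
15–60 m wide, matching the published mound dimensions), seeded Gaussian
noise, a coarse current field, and live-coral labels drawn Bernoulli from
a logistic model over z-scored attributes (defaults: MaxWD 1.5, Max_Rug
1, Index 1, MaxCurrent −0.5). Present features receive a coral disc on
their up-current flank sized to `coral_cover_rule` (default 0.3) of the
feature area. The registry records each mound's parameters and footprint
(cells where the mound term reaches **0.2 m**); `score_recovery()`
attributes a delineated feature to a mound when at least half the
feature's cells fall in that footprint.

The reference scene (700×1000 cells at 2 m, 120 mounds, seed 42) is
recovered perfectly by the default thresholds — 120 features, all
one-to-one, zero spurious — both noise-free and at 0.3 m noise, in a few
seconds on one CPU.

## Known limitations

* **Raster-only geometry.** No GDAL/GEOS binding: raster I/O is ESRI
  ASCII (GeoTIFF requests raise an informative error), vector output is
  GeoJSON in the grid's projected coordinates, and all overlay operations
  are performed on the grid.
* **Orientation quantisation.** `MBG_Orient` is the minimum-area
  rectangle orientation of the *rasterised* outline. For a long axis
  tilted only slightly (≲15°) off a grid axis, the staircase genuinely
  makes the axis-aligned box minimal and the orientation snaps to
  0°/90°; for small mounds (short axis under ~6 cells) errors up to
  ~20° occur. For resolved elongated mounds (sigmas of 6–8 × 15–20 m at
  2 m cells, azimuth ≥ 20° off-axis) recovery is within 10°, typically
  1–6°.
* **Relief from delineated outlines.** A BPI-threshold outline stops
  partway down the mound flank, so `MaxVRelief` measured inside it
  understates the full planted height; measured over the planted
  footprint the bias is only the 0.2 m footprint cutoff plus rim
  quantisation (|error| < 0.5 m in the tests).
* **Merged features are flagged, not resolved.** As in the original
  semi-automatic workflow, outlines that touch after buffering are left
  for manual editing.
* **Current join is nearest-cell.** No interpolation of the coarse
  hydrodynamic field; each feature takes the value under its centroid.
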