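Package: moundr
Title: Semi-Automatic Delineation of Seabed Coral Mounds and Prediction of
    Live Coral Presence from Bathymetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Raster terrain toolbox for mapping small positive-relief seabed
    features ("mini-mounds") from multibeam bathymetry and modelling the
    likelihood that they carry live cold-water coral framework. Computes the
    bathymetric positioning index (BPI) over an annular neighbourhood,
    delineates candidate mounds by BPI thresholding with area and shape
    filters, characterises every feature with a standard set of morphometric
    and acoustic attributes (water depths, vertical relief, minimum bounding
    rectangle, rugosity, backscatter, reconstructed pre-mound slope), joins
    coarse current-speed data and manually mapped live-coral cover, and fits a
    random-forest classifier of coral presence with permutation importance,
    partial-dependence response curves, confusion-matrix and ROC evaluation,
    and a per-feature predictive map. Includes a synthetic-scene generator
    (sloping ridge, planted anisotropic Gaussian mounds, noise, logistic
    presence labels) so the full pipeline can be exercised end-to-end with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    mgcv,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
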