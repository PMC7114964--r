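#' Bathymetric positioning index
#'
#' BPI is the elevation of a cell minus the mean elevation over an annular
#' neighbourhood around it: positive values are locations shallower than their
#' surroundings (ridges, mounds), negative values are locations deeper than
#' their surroundings (depressions), and values near zero are flats or
#' constant slopes. The default annulus (inner radius 8, outer radius 24
#' cells, i.e. "i8 x o24") matches the scale of the Mingulay mini-mounds at
#' 2 m cells; radii are configurable through `annulus`. Raw BPI values are
#' used directly (no standardisation), since the delineation thresholds are
#' expressed in raw units.
#'
#' @param grid a `moundr_grid` of elevation (metres, up-positive).
#' @param annulus an [annulus_spec()]; default `annulus_spec(8, 24)`.
#' @param min_valid_fraction passed to [focal_mean_annulus()].
#' @return a `moundr_grid` of BPI values; nodata where the focal mean is
#'   undefined.
#' @export
compute_bpi <- function(grid, annulus = annulus_spec(8L, 24L),
                        min_valid_fraction = 0.5) {
  stopifnot_grid(grid)
  fm <- focal_mean_annulus(grid, annulus, min_valid_fraction)
  grid_like(grid, grid$values - fm$values)
}
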