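# Model constants. All of these are surfaced through function arguments or
# the pipeline config; the values here are the package defaults.

#' Land-cover class codes
#'
#' Integer codes used on every reclassified land-cover grid: eight classes
#' covering the major row crops, the natural covers that provide pollinator
#' forage, an "other crops" catch-all, and a nodata code.
#'
#' @return Named integer vector mapping class name to raster code.
#' @export
#' @examples
#' class_codes()[["grassland"]]
class_codes <- function() {
  c(
    nodata = -999L, corn = 1L, wheat = 3L, soybeans = 5L,
    forest = 63L, wetland = 83L, grassland = 176L, other_crops = 254L
  )
}

#' Natural-cover and cropland code sets
#'
#' Natural covers (grassland, herbaceous wetland, forest) are scored as
#' habitat (quality 1) and are the pollinator forage base; all cropland
#' classes are scored 0.
#'
#' @return Integer vector of raster codes.
#' @export
natural_codes <- function() {
  unname(class_codes()[c("forest", "wetland", "grassland")])
}

#' @rdname natural_codes
#' @export
crop_codes <- function() {
  unname(class_codes()[c("corn", "wheat", "soybeans", "other_crops")])
}

# crops that receive quantified insecticide use (the "primary crops")
primary_crops <- function() c("corn", "wheat", "soybeans")

#' Fixed denominator of the site Quality Index
#'
#' Number of 30-m pixels inside one interior 1609-m foraging buffer under
#' the calibrated polygonal rasterization (see [build_buffer_mask()]). Used
#' as the fixed denominator of the Quality Index even for edge-truncated
#' buffers.
#' @export
QI_DENOMINATOR <- 9018L

#' Foraging buffer radius in meters (1.6 km core flight area)
#' @export
BUFFER_RADIUS_M <- 1609

# Calibrated buffer rasterization: an inscribed regular polygon with this
# many segments, first vertex rotated by BUFFER_ROT_FRAC of one segment.
# Calibrated once so that an interior site on a 30-m grid covers exactly
# QI_DENOMINATOR cell centers (a pure circle covers 9033; no 4-fold
# symmetric shape can give 9018 since symmetric counts are 1 mod 4).
BUFFER_SEGMENTS <- 69L
BUFFER_ROT_FRAC <- 0.2

#' Spray-drift kernel parameters
#'
#' Maximum drift distance (meters) and the exponential decay coefficient.
#' The kernel is `exp(-DECAY_COEF / D_MAX_M * d)` truncated at `D_MAX_M`.
#' The coefficient is `-ln(0.05)` (about 2.996, commonly rounded to 3) so
#' that exactly 95% of spray material is deposited within the maximum
#' distance and the residual factor at `D_MAX_M` is 5%.
#' @export
D_MAX_M <- 60

#' @rdname D_MAX_M
#' @export
DECAY_COEF <- -log(0.05)

#' Hectares per 30-m pixel
#' @export
HA_PER_PIXEL <- 0.09

# InVEST-style quality transform defaults: fixed exponent z, configurable
# half-saturation constant k (degradation level halving quality).
QUALITY_Z <- 2.5
QUALITY_K <- 0.5

# Bee-REX style conversion from a field application rate to a per-bee dose:
# 2.7 ug/bee per lb a.i./acre for foliar spray, times 0.892179 (lb/acre per
# kg/ha). Its absolute value cancels under the max-normalization used for
# threat weights, but it is kept explicit so risk quotients have meaning.
BEEREX_DOSE_FACTOR <- 2.7 * 0.892179

#' Insecticide compound table
#'
#' The eight insecticides tracked by the pipeline with their chemical class
#' and primary mode of application. Seed-treated neonicotinoids are included
#' in use-trend analysis but refused as drift-threat layers (only foliar
#' sprays are modelled as a threat to adjacent natural covers).
#'
#' @return A tibble with columns `compound`, `class`, `mode`.
#' @export
#' @examples
#' compound_table()
compound_table <- function() {
  tibble::tribble(
    ~compound,            ~class,            ~mode,
    "Chlorpyrifos",       "Organophosphate", "Spray",
    "Esfenvalerate",      "Pyrethroid",      "Spray",
    "Cyhalothrin-lambda", "Pyrethroid",      "Spray",
    "Bifenthrin",         "Pyrethroid",      "Spray",
    "Cyfluthrin",         "Pyrethroid",      "Spray",
    "Clothianidin",       "Neonicotinoid",   "Seed",
    "Thiamethoxam",       "Neonicotinoid",   "Seed",
    "Imidacloprid",       "Neonicotinoid",   "Seed"
  )
}

# foliar (spray) compounds eligible for threat modelling
foliar_compounds <- function() {
  tbl <- compound_table()
  tbl$compound[tbl$mode == "Spray"]
}
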