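# Drift-threat layers for foliar insecticides. Each (compound, crop)
# combination becomes a raster of relative threat intensity on treated
# (non-organic) crop pixels, with a compound-level weight derived from
# honey-bee risk quotients (estimated dose / LD50). Seed-treated
# compounds are excluded: only foliar sprays are modelled as a drift
# threat to adjacent natural covers.

#' Risk quotient from an application rate and LD50
#'
#' Converts a field application rate to an estimated per-bee dose using a
#' fixed Bee-REX style conversion (2.7 ug/bee per lb a.i./acre, i.e.
#' about 2.409 ug/bee per kg/ha) and divides by the acute LD50. The
#' absolute value of the conversion factor cancels under the
#' max-normalization used for threat weights, but is kept explicit so
#' quotients are interpretable hazard screens.
#'
#' @param rate Application rate in kg/ha (>= 0).
#' @param ld50 Acute LD50 in ug/bee (> 0).
#' @param exposure `"contact"` or `"oral"` (labels the quotient; the dose
#'   conversion is the same screening constant for both routes).
#' @param dose_factor ug/bee dose per 1 kg/ha applied.
#' @return Dimensionless risk quotient, 0 iff `rate` is 0.
#' @export
#' @examples
#' compute_risk_quotient(1, ld50 = 2)
compute_risk_quotient <- function(rate, ld50, exposure = c("contact", "oral"),
                                  dose_factor = BEEREX_DOSE_FACTOR) {
  exposure <- match.arg(exposure)
  if (any(ld50 <= 0)) stop("`ld50` must be positive", call. = FALSE)
  if (any(rate < 0)) stop("`rate` must be non-negative", call. = FALSE)
  rate * dose_factor / ld50
}

#' Representative acute LD50 table for the foliar compounds
#'
#' Oral and contact acute LD50 values (ug/bee) for the four foliar-applied
#' insecticides modelled as drift threats. These are representative
#' honey-bee toxicity values of the kind tabulated in standard
#' ecotoxicology screens; threat weights depend only on their ratios, not
#' their absolute scale.
#'
#' @return Tibble `compound`, `ld50_oral`, `ld50_contact` (ug/bee).
#' @export
default_ld50_table <- function() {
  tibble::tribble(
    ~compound,            ~ld50_oral, ~ld50_contact,
    "Chlorpyrifos",       0.25,       0.059,
    "Esfenvalerate",      0.13,       0.017,
    "Cyhalothrin-lambda", 0.91,       0.038,
    "Bifenthrin",         0.10,       0.015,
    "Cyfluthrin",         0.05,       0.001
  )
}

#' Risk-quotient table for a set of compounds
#'
#' Computes oral and contact risk quotients for each compound at a
#' reference application rate (the compound's statewide mean rate, or 1
#' kg/ha by default) and combines them. The default combination takes the
#' maximum of the two routes as a conservative hazard screen.
#'
#' @param ld50 Tibble from [default_ld50_table()] (columns `compound`,
#'   `ld50_oral`, `ld50_contact`).
#' @param rates Optional tibble `compound`, `rate_kg_ha` of reference
#'   rates; defaults to 1 kg/ha for all compounds.
#' @param combine `"max"`, `"oral"`, or `"contact"`.
#' @return Tibble `compound`, `rq_oral`, `rq_contact`, `rq`.
#' @export
risk_quotient_table <- function(ld50 = default_ld50_table(), rates = NULL,
                                combine = c("max", "oral", "contact")) {
  combine <- match.arg(combine)
  tbl <- ld50
  if (is.null(rates)) {
    tbl$rate_kg_ha <- 1
  } else {
    tbl <- dplyr::left_join(tbl, rates, by = "compound")
    tbl$rate_kg_ha[is.na(tbl$rate_kg_ha)] <- 0
  }
  tbl$rq_oral <- compute_risk_quotient(tbl$rate_kg_ha, tbl$ld50_oral, "oral")
  tbl$rq_contact <- compute_risk_quotient(tbl$rate_kg_ha, tbl$ld50_contact, "contact")
  tbl$rq <- switch(combine,
    max = pmax(tbl$rq_oral, tbl$rq_contact),
    oral = tbl$rq_oral,
    contact = tbl$rq_contact
  )
  tbl[, c("compound", "rq_oral", "rq_contact", "rq")]
}

#' Threat weights from risk quotients
#'
#' Max-normalizes the combined risk quotients so weights lie in `[0, 1]`
#' with the most hazardous compound at exactly 1. If every quotient is
#' zero, all weights are zero (with a warning).
#'
#' @param rq_table Tibble with `compound` and `rq` columns (see
#'   [risk_quotient_table()]).
#' @return Tibble `compound`, `weight`.
#' @export
#' @examples
#' threat_weight(data.frame(compound = c("a", "b"), rq = c(2, 4)))
threat_weight <- function(rq_table) {
  rq <- rq_table$rq
  if (length(rq) == 0) {
    return(tibble::tibble(compound = character(), weight = numeric()))
  }
  if (any(rq < 0)) stop("risk quotients must be non-negative", call. = FALSE)
  mx <- max(rq)
  if (mx == 0) {
    warning("all risk quotients are zero; all threat weights set to 0")
    w <- rep(0, length(rq))
  } else {
    w <- rq / mx
  }
  tibble::tibble(compound = rq_table$compound, weight = w)
}

#' Build a threat raster for one insecticide-crop combination
#'
#' The threat intensity on a non-organic pixel of crop `crop` is the
#' district application rate of `compound` on that crop, max-normalized
#' to `[0, 1]` across districts (within the compound-crop-year), and 0
#' everywhere else. Organic fields are exempt. Seed-treated compounds are
#' refused: only foliar sprays are modelled as drift threats.
#'
#' @param landcover Reclassified land-cover `bee_grid`.
#' @param organic Logical organic-farm mask (or NULL).
#' @param district_map Integer district-id `bee_grid` (or NULL for one
#'   district).
#' @param compound Compound name (must have Mode "Spray" in
#'   [compound_table()]).
#' @param crop Crop class name (`"corn"`, `"wheat"`, `"soybeans"`,
#'   `"other_crops"`).
#' @param rates Rate tibble from [district_application_rates()].
#' @param year Year to select from `rates`.
#' @param weight Compound threat weight in `[0, 1]` (from
#'   [threat_weight()]); default 1.
#' @param compounds Compound metadata table (default [compound_table()]).
#' @return A `threat_layer`: list with `intensity` (`bee_grid` in
#'   `[0, 1]`), `compound`, `crop`, `weight`, `max_distance` (60 m),
#'   `decay` (`"exponential"`).
#' @export
build_threat_raster <- function(landcover, organic = NULL, district_map = NULL,
                                compound, crop, rates, year,
                                weight = 1, compounds = compound_table()) {
  mode <- compounds$mode[compounds$compound == compound]
  if (length(mode) == 1 && mode != "Spray") {
    stop(sprintf(
      "%s is a seed-treated compound; only foliar sprays are modelled as drift threats",
      compound
    ), call. = FALSE)
  }
  if (is.null(organic)) {
    organic <- grid_like(landcover, matrix(FALSE, nrow(landcover), ncol(landcover)))
  }
  if (is.null(district_map)) {
    district_map <- grid_like(landcover, matrix(1L, nrow(landcover), ncol(landcover)))
  }
  stopifnot_aligned(landcover, organic)
  stopifnot_aligned(landcover, district_map)
  crop_code <- class_codes()[[crop]]

  r <- rates[rates$compound == compound & rates$crop == crop &
    rates$year == year, , drop = FALSE]
  rate_by_district <- stats::setNames(r$rate_kg_ha, r$district)
  mx <- if (nrow(r)) max(r$rate_kg_ha) else 0

  intensity <- matrix(0, nrow(landcover), ncol(landcover))
  if (mx > 0) {
    on_crop <- unclass(landcover) == crop_code & !unclass(organic)
    d <- as.character(unclass(district_map)[on_crop])
    v <- rate_by_district[d] / mx
    v[is.na(v)] <- 0
    intensity[on_crop] <- v
  }
  structure(
    list(
      intensity = grid_like(landcover, intensity),
      compound = compound, crop = crop, weight = weight,
      max_distance = D_MAX_M, decay = "exponential"
    ),
    class = "threat_layer"
  )
}

#' Build every foliar threat layer for one year
#'
#' One layer per foliar compound and primary crop, weighted by the
#' risk-quotient-derived compound weights.
#'
#' @inheritParams build_threat_raster
#' @param rq_table Risk-quotient tibble (default
#'   [risk_quotient_table()]).
#' @param crops Crop class names to model.
#' @return A list of `threat_layer` objects.
#' @export
build_threat_layers <- function(landcover, organic = NULL, district_map = NULL,
                                rates, year,
                                rq_table = risk_quotient_table(),
                                crops = primary_crops(),
                                compounds = compound_table()) {
  w <- threat_weight(rq_table)
  foliar <- intersect(w$compound, foliar_compounds())
  combos <- tidyr::expand_grid(compound = foliar, crop = crops)
  purrr::pmap(combos, function(compound, crop) {
    build_threat_raster(
      landcover, organic, district_map, compound, crop, rates, year,
      weight = w$weight[w$compound == compound], compounds = compounds
    )
  })
}

#' @export
print.threat_layer <- function(x, ...) {
  cat(sprintf(
    "<threat_layer> %s on %s: weight %.3f, max distance %g m (%s decay)\n",
    x$compound, x$crop, x$weight, x$max_distance, x$decay
  ))
  invisible(x)
}
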