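# Pesticide-use apportionment and trends. County use estimates are
# apportioned to crop-specific district application rates
# (AP = sum of county use in the district * pesticide-crop ratio /
# district planted area), multiplied by the crop area inside the
# dissolved apiary-buffer footprint to give buffer totals
# (TP = sum over crops and districts of AP * BF), and the annual totals
# are screened for linear trends by ordinary least squares with
# zero-use years treated as missing.

#' District application rates (kg/ha)
#'
#' For every (compound, crop, district, year): sums the county-level low
#' use estimates over the district's counties, multiplies by the
#' pesticide-crop use ratio, and divides by the district planted area of
#' that crop. Missing ratios are treated as 0 with a message; a zero
#' planted area facing a nonzero numerator is an error.
#'
#' @param tables A `pesticide_tables` list (or any list with tibbles
#'   `use` (county, year, compound, kg), `ratios` (compound, crop, year,
#'   ratio), `areas` (district, crop, year, hectares), `lookup`
#'   (county, district)).
#' @return A tibble `compound`, `crop`, `district`, `year`,
#'   `rate_kg_ha`.
#' @export
#' @examples
#' tabs <- generate_pesticide_tables(simulation_config(use_noise_sd = 0))
#' head(district_application_rates(tabs))
district_application_rates <- function(tables) {
  use <- tables$use
  ratios <- tables$ratios
  areas <- tables$areas
  lookup <- tables$lookup
  stopifnot(all(use$kg >= 0), all(areas$hectares >= 0))

  district_use <- use |>
    dplyr::inner_join(lookup, by = "county") |>
    dplyr::group_by(.data$compound, .data$district, .data$year) |>
    dplyr::summarise(district_kg = sum(.data$kg), .groups = "drop")

  grid <- tidyr::expand_grid(
    compound = unique(use$compound),
    crop = unique(areas$crop),
    district = unique(lookup$district),
    year = unique(use$year)
  )
  out <- grid |>
    dplyr::left_join(district_use, by = c("compound", "district", "year")) |>
    dplyr::left_join(ratios, by = c("compound", "crop", "year")) |>
    dplyr::left_join(areas, by = c("district", "crop", "year"))

  n_missing_ratio <- sum(is.na(out$ratio) & !is.na(out$district_kg) &
    out$district_kg > 0)
  if (n_missing_ratio > 0) {
    message(sprintf(
      "district_application_rates: %d compound-crop-year combinations have no ratio (treated as 0)",
      n_missing_ratio
    ))
  }
  out$ratio[is.na(out$ratio)] <- 0
  out$district_kg[is.na(out$district_kg)] <- 0

  numer <- out$district_kg * out$ratio
  bad <- (is.na(out$hectares) | out$hectares <= 0) & numer > 0
  if (any(bad)) {
    stop("zero or missing planted area with nonzero apportioned use for: ",
      paste(utils::head(unique(paste(out$compound[bad], out$crop[bad],
        out$district[bad], out$year[bad]
      )), 3), collapse = "; "),
      call. = FALSE
    )
  }
  out$rate_kg_ha <- ifelse(numer == 0, 0, numer / out$hectares)
  stopifnot(all(is.finite(out$rate_kg_ha)), all(out$rate_kg_ha >= 0))
  out[, c("compound", "crop", "district", "year", "rate_kg_ha")]
}

#' Total pesticide use inside the buffer footprint (kg)
#'
#' The buffer total for compound `i` in year `t` is the sum over crops
#' and districts of the application rate times the crop area inside the
#' dissolved apiary-buffer footprint. BF keys absent from the rate table
#' contribute zero (with a message), matching the treatment of unreported
#' use.
#'
#' @param rates Tibble from [district_application_rates()].
#' @param bf Tibble with `district`, `crop`, `hectares` (one year's
#'   footprint crop areas, from [crop_area_in_footprint()]), or with an
#'   additional `year` column for multi-year tables.
#' @param years Years to evaluate; defaults to all years in `rates`.
#' @return A tibble `compound`, `year`, `total_kg`.
#' @export
total_use_in_buffers <- function(rates, bf, years = unique(rates$year)) {
  if (!"year" %in% names(bf)) {
    bf <- tidyr::expand_grid(year = years) |>
      dplyr::cross_join(bf)
  }
  bf <- bf[bf$year %in% years, , drop = FALSE]
  joined <- dplyr::left_join(
    bf, rates,
    by = c("district", "crop", "year"),
    relationship = "many-to-many"
  )
  n_unmatched <- sum(is.na(joined$rate_kg_ha))
  if (n_unmatched > 0) {
    message(sprintf(
      "total_use_in_buffers: %d footprint crop areas had no matching rate (contribute 0)",
      n_unmatched
    ))
    joined <- joined[!is.na(joined$rate_kg_ha), , drop = FALSE]
  }
  tidyr::expand_grid(
    compound = unique(rates$compound), year = sort(unique(years))
  ) |>
    dplyr::left_join(
      joined |>
        dplyr::group_by(.data$compound, .data$year) |>
        dplyr::summarise(
          total_kg = sum(.data$rate_kg_ha * .data$hectares),
          .groups = "drop"
        ),
      by = c("compound", "year")
    ) |>
    dplyr::mutate(total_kg = dplyr::coalesce(.data$total_kg, 0))
}

#' Average use per apiary site
#'
#' @param total_kg Total buffer use (kg), scalar or vector.
#' @param n_sites Number of registered sites in that year (>= 1).
#' @return kg per site.
#' @export
#' @examples
#' per_site_average(8867.2, 13477)
per_site_average <- function(total_kg, n_sites) {
  if (any(n_sites < 1)) stop("`n_sites` must be at least 1", call. = FALSE)
  total_kg / n_sites
}

#' Statewide annual totals from the county use table
#'
#' Sums the county-level estimates over all counties per compound and
#' year: the series the configured synthetic trend slopes refer to.
#'
#' @param tables A `pesticide_tables` list.
#' @return Tibble `compound`, `year`, `total_kg`.
#' @export
statewide_totals <- function(tables) {
  tables$use |>
    dplyr::group_by(.data$compound, .data$year) |>
    dplyr::summarise(total_kg = sum(.data$kg), .groups = "drop")
}

#' Fit a linear use trend
#'
#' Ordinary least squares of annual total use against year, with zero-use
#' years treated as missing and removed before fitting. At least three
#' nonzero years are required; otherwise the trend is reported as not
#' estimable (NA slope). Significance is a two-sided t-test on the slope
#' at level `alpha`.
#'
#' @param series A data frame with columns `year` and `total_kg` (a
#'   `compound` column, if present, labels the output).
#' @param alpha Significance level (default 0.05).
#' @return A `use_trend` object; see [tidy.use_trend()].
#' @export
#' @examples
#' fit_use_trend(data.frame(year = 2001:2010, total_kg = 10 + 5 * (0:9)))
fit_use_trend <- function(series, alpha = 0.05) {
  compound <- if ("compound" %in% names(series)) series$compound[[1]] else NA_character_
  nz <- series[series$total_kg > 0 & !is.na(series$total_kg), , drop = FALSE]
  if (nrow(nz) < 3) {
    out <- list(
      compound = compound, slope = NA_real_, intercept = NA_real_,
      p_value = NA_real_, n_years = nrow(nz), alpha = alpha,
      significant = NA, estimable = FALSE
    )
    return(structure(out, class = "use_trend"))
  }
  fit <- stats::lm(total_kg ~ year, data = nz)
  # an exactly linear or constant series triggers a harmless
  # "essentially perfect fit" warning from summary.lm
  sfit <- suppressWarnings(summary(fit))
  sm <- sfit$coefficients
  slope <- unname(sm["year", "Estimate"])
  p <- unname(sm["year", "Pr(>|t|)"])
  if (is.nan(p)) p <- 1 # exactly constant series: zero slope, no evidence
  structure(
    list(
      compound = compound, slope = slope,
      intercept = unname(sm["(Intercept)", "Estimate"]),
      p_value = p, n_years = nrow(nz), alpha = alpha,
      significant = p < alpha, estimable = TRUE,
      r_squared = sfit$r.squared
    ),
    class = "use_trend"
  )
}

#' Fit use trends for every compound
#'
#' @param totals Tibble `compound`, `year`, `total_kg` (e.g. from
#'   [total_use_in_buffers()]).
#' @param alpha Significance level.
#' @return A tibble with one row per compound: slope (kg/yr), intercept,
#'   p-value, number of nonzero years, and significance flag.
#' @export
fit_use_trends <- function(totals, alpha = 0.05) {
  totals |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_map(~ tidy.use_trend(fit_use_trend(
      dplyr::mutate(.x, compound = .y$compound), alpha
    ))) |>
    dplyr::bind_rows()
}

#' @export
print.use_trend <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf(
      "<use_trend> %s: not estimable (%d nonzero years)\n",
      x$compound, x$n_years
    ))
  } else {
    cat(sprintf(
      "<use_trend> %s: slope %.1f kg/yr (p = %.3g, n = %d)%s\n",
      x$compound, x$slope, x$p_value, x$n_years,
      if (isTRUE(x$significant)) " *" else ""
    ))
  }
  invisible(x)
}

#' Tidy a fitted use trend
#'
#' @param x A `use_trend` from [fit_use_trend()].
#' @param ... Unused.
#' @return One-row tibble: `compound`, `slope_kg_yr`, `intercept`,
#'   `p_value`, `n_years`, `significant`.
#' @export
tidy.use_trend <- function(x, ...) {
  tibble::tibble(
    compound = x$compound, slope_kg_yr = x$slope, intercept = x$intercept,
    p_value = x$p_value, n_years = x$n_years, significant = x$significant
  )
}

#' @rdname tidy.use_trend
#' @export
glance.use_trend <- function(x, ...) {
  tibble::tibble(
    r_squared = if (x$estimable) x$r_squared else NA_real_,
    n_years = x$n_years, alpha = x$alpha, estimable = x$estimable
  )
}
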