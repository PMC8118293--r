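# Per-site indices over the foraging buffer. The Quality Index averages
# pixel quality over a site's 1.6-km buffer with the fixed 9018-pixel
# denominator, so it mixes habitat amount and habitat degradation. The
# Degradation Index averages the quality deficit (1 - Q) over the
# natural-cover pixels only, isolating the pesticide effect from
# land-cover amount.

#' Site Quality Index
#'
#' `QI = sum of Q over the buffer / QI_DENOMINATOR`. The denominator is
#' fixed at 9018 (the interior-buffer pixel count) regardless of the
#' actual mask count, so edge-truncated buffers are penalized exactly as
#' the index defines.
#'
#' @param mask Logical buffer `bee_grid` from [build_buffer_mask()].
#' @param Q Quality `bee_grid`.
#' @param denominator Fixed pixel denominator (default
#'   [QI_DENOMINATOR]).
#' @return QI in `[0, 1]`.
#' @export
quality_index <- function(mask, Q, denominator = QI_DENOMINATOR) {
  stopifnot_aligned(mask, Q)
  if (!any(mask)) stop("empty buffer mask", call. = FALSE)
  sum(unclass(Q)[unclass(mask)]) / denominator
}

#' Site Degradation Index
#'
#' `DI = mean of (1 - Q)` over the natural-cover pixels (grassland,
#' wetland, forest) inside the buffer: the deviation from pesticide-free
#' status of the natural covers present. Missing (NA) when the buffer
#' contains no natural pixels.
#'
#' @param mask Logical buffer `bee_grid`.
#' @param Q Quality `bee_grid`.
#' @param landcover Reclassified land-cover `bee_grid`.
#' @return A list with `di` (in `[0, 1]` or NA) and `n_natural`.
#' @export
degradation_index <- function(mask, Q, landcover) {
  stopifnot_aligned(mask, Q)
  stopifnot_aligned(mask, landcover)
  natural <- unclass(mask) & (unclass(landcover) %in% natural_codes())
  n <- sum(natural)
  if (n == 0) {
    return(list(di = NA_real_, n_natural = 0L))
  }
  list(di = sum(1 - unclass(Q)[natural]) / n, n_natural = n)
}

#' Per-site index records for one year
#'
#' Computes QI and DI independently for every site (overlapping buffers
#' are evaluated per site; the dissolved footprint is only used for mass
#' totals).
#'
#' @param sites Tibble `site_id`, `x`, `y`.
#' @param landcover Reclassified land-cover `bee_grid`.
#' @param Q Quality `bee_grid`.
#' @param year Year label for the records.
#' @param radius Buffer radius in meters.
#' @param masks Optional precomputed list of buffer masks (named by
#'   site_id) to avoid rebuilding them per year.
#' @return Tibble `site_id`, `year`, `qi`, `di`, `n_natural`.
#' @export
site_indices <- function(sites, landcover, Q, year,
                         radius = BUFFER_RADIUS_M, masks = NULL) {
  if (is.null(masks)) {
    masks <- build_buffer_masks(sites, landcover, radius)
  }
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    m <- masks[[as.character(sites$site_id[i])]]
    d <- degradation_index(m, Q, landcover)
    tibble::tibble(
      site_id = sites$site_id[i], year = year,
      qi = quality_index(m, Q), di = d$di, n_natural = d$n_natural
    )
  })
}

#' Statewide index summaries with year-over-year change
#'
#' Means across sites per year with a normal-approximation 95% CI
#' halfwidth (`1.96 * sd / sqrt(n)`) and percent change relative to a
#' reference year, `(mean_year - mean_ref) / mean_ref * 100` (negative
#' for declines). Sites with missing DI (no natural pixels) are excluded
#' from the DI mean, with a message reporting the count.
#'
#' @param records Tibble from [site_indices()] (site_id, year, qi, di).
#' @param reference_year Year changes are computed against (default the
#'   earliest year present).
#' @return Tibble `index` (`"qi"`/`"di"`), `year`, `mean`, `ci95`, `n`,
#'   `pct_change`.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   site_id = rep(c("a", "b"), 2), year = rep(c(2006, 2014), each = 2),
#'   qi = c(0.48, 0.49, 0.42, 0.436), di = c(0.09, 0.1046, 0.19, 0.19)
#' )
#' summarize_indices(recs, reference_year = 2006)
summarize_indices <- function(records, reference_year = min(records$year)) {
  n_missing <- sum(is.na(records$di))
  if (n_missing > 0) {
    message(sprintf(
      "summarize_indices: %d site-years with no natural pixels excluded from DI",
      n_missing
    ))
  }
  long <- records |>
    tidyr::pivot_longer(c("qi", "di"), names_to = "index", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  out <- long |>
    dplyr::group_by(.data$index, .data$year) |>
    dplyr::summarise(
      mean = mean(.data$value),
      ci95 = 1.96 * stats::sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    )
  ref <- out |>
    dplyr::filter(.data$year == reference_year) |>
    dplyr::select("index", ref_mean = "mean")
  out |>
    dplyr::left_join(ref, by = "index") |>
    dplyr::mutate(
      pct_change = (.data$mean - .data$ref_mean) / .data$ref_mean * 100
    ) |>
    dplyr::select(-"ref_mean") |>
    dplyr::arrange(.data$index, .data$year)
}

#' Per-site change in Quality Index between two years
#'
#' @param records Tibble from [site_indices()] across years.
#' @param year_a,year_b Years to difference (`delta = QI_b - QI_a`).
#' @param sites Optional site table (`site_id`, `x`, `y`) to attach
#'   coordinates for mapping.
#' @return Tibble `site_id`, `qi_a`, `qi_b`, `delta_qi` (plus `x`, `y`
#'   when `sites` is given). Sites missing either year are excluded with
#'   a message.
#' @export
site_delta_map <- function(records, year_a, year_b, sites = NULL) {
  a <- records[records$year == year_a, c("site_id", "qi")]
  b <- records[records$year == year_b, c("site_id", "qi")]
  merged <- dplyr::inner_join(a, b, by = "site_id", suffix = c("_a", "_b"))
  dropped <- length(union(a$site_id, b$site_id)) - nrow(merged)
  if (dropped > 0) {
    message(sprintf(
      "site_delta_map: %d sites missing from one of the years (excluded)",
      dropped
    ))
  }
  out <- merged |>
    dplyr::mutate(delta_qi = .data$qi_b - .data$qi_a) |>
    dplyr::rename(qi_a = "qi_a", qi_b = "qi_b")
  if (!is.null(sites)) {
    out <- dplyr::left_join(out, sites[, c("site_id", "x", "y")], by = "site_id")
  }
  out
}

#' Plot statewide index trajectories
#'
#' Means with 95% CI ribbons per index across years.
#'
#' @param summary Tibble from [summarize_indices()].
#' @return A ggplot object.
#' @export
plot_index_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$year, y = .data$mean,
    ymin = .data$mean - .data$ci95, ymax = .data$mean + .data$ci95,
    color = .data$index, fill = .data$index
  )) +
    ggplot2::geom_ribbon(alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "year", y = "index mean (95% CI)") +
    ggplot2::ylim(0, 1)
}
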