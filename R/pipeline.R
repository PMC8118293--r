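# One-config orchestration of the whole analysis: simulate -> reclassify
# -> buffers -> rates -> threats -> quality -> indices, with reproducible
# outputs and a manifest recording every constant used.

#' Pipeline configuration
#'
#' Bundles the synthetic-world settings with every model constant so a
#' run is fully described by one object. All constants default to the
#' package values and are echoed into the run manifest.
#'
#' @param sim A [simulation_config()].
#' @param radius Buffer radius (m).
#' @param qi_denominator Fixed Quality Index denominator (pixels).
#' @param d_max Maximum drift distance (m).
#' @param k Half-saturation constant of the quality transform.
#' @param z Quality transform exponent.
#' @param alpha Trend significance level.
#' @param rq_combine How oral/contact risk quotients combine
#'   (`"max"`, `"oral"`, `"contact"`).
#' @param threat_compounds Compounds to model as drift threats (default:
#'   the foliar compounds).
#' @param compounds Compound metadata table (default [compound_table()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            radius = BUFFER_RADIUS_M,
                            qi_denominator = QI_DENOMINATOR,
                            d_max = D_MAX_M,
                            k = QUALITY_K,
                            z = QUALITY_Z,
                            alpha = 0.05,
                            rq_combine = "max",
                            threat_compounds = foliar_compounds(),
                            compounds = compound_table()) {
  structure(
    list(
      sim = sim, radius = radius, qi_denominator = qi_denominator,
      d_max = d_max, k = k, z = z, alpha = alpha, rq_combine = rq_combine,
      threat_compounds = threat_compounds, compounds = compounds
    ),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Report-only: returns a tibble of problems (empty when the config is
#' valid). Seed-treated compounds requested as threat layers are flagged
#' as refusals (only foliar sprays are modelled as drift threats);
#' non-positive constants are flagged as unit errors.
#'
#' @param config A [pipeline_config()].
#' @return Tibble `field`, `issue`, `severity`.
#' @export
#' @examples
#' validate_config(pipeline_config())
validate_config <- function(config) {
  report <- tibble::tibble(
    field = character(), issue = character(), severity = character()
  )
  add <- function(field, issue, severity = "error") {
    report <<- dplyr::bind_rows(report, tibble::tibble(
      field = field, issue = issue, severity = severity
    ))
  }
  if (!inherits(config$sim, "simulation_config")) {
    add("sim", "not a simulation_config")
  } else {
    if (length(config$sim$years) == 0) add("sim$years", "no assessment years")
    missing_cp <- setdiff(names(config$sim$use_slopes), config$compounds$compound)
    if (length(missing_cp) > 0) {
      add(
        "sim$use_slopes",
        paste("compounds absent from compound table:", paste(missing_cp, collapse = ", "))
      )
    }
    if (!all(config$sim$years %in% config$sim$use_years)) {
      add("sim$years", "assessment years not covered by use_years")
    }
  }
  for (fld in c("radius", "d_max", "k", "z", "qi_denominator")) {
    if (!is.numeric(config[[fld]]) || config[[fld]] <= 0) {
      add(fld, "must be a positive number (unit error)")
    }
  }
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    add("alpha", "must lie in (0, 1)")
  }
  seed_req <- config$threat_compounds[
    config$threat_compounds %in%
      config$compounds$compound[config$compounds$mode == "Seed"]
  ]
  for (cp in seed_req) {
    add(
      "threat_compounds",
      sprintf("%s is seed-treated: refused for threat modelling", cp),
      severity = "refusal"
    )
  }
  unknown <- setdiff(config$threat_compounds, config$compounds$compound)
  if (length(unknown) > 0) {
    add(
      "threat_compounds",
      paste("unknown compounds:", paste(unknown, collapse = ", "))
    )
  }
  report
}

#' Run the full pipeline
#'
#' Generates the synthetic world, computes application rates, buffer
#' totals and trends, builds threat layers and the quality model per
#' assessment year, and summarises per-site indices. When `out_dir` is
#' given, writes per-year rasters (`.asc`), CSV tables, GeoJSON sites,
#' and a JSON manifest recording the seed, constants, config hash and
#' output sizes; outputs are byte-identical across runs with the same
#' config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed), or NULL to skip
#'   writing.
#' @return Invisibly, a list with all intermediate and final products
#'   plus the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  report <- validate_config(config)
  errs <- report[report$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop(
      "invalid pipeline config:\n",
      paste(sprintf("  %s: %s", errs$field, errs$issue), collapse = "\n"),
      call. = FALSE
    )
  }
  for (i in which(report$severity == "refusal")) {
    message("run_pipeline: ", report$issue[i])
  }
  sim <- config$sim
  years <- sim$years

  # --- stage 1: synthetic world -------------------------------------------
  landcover <- stats::setNames(
    lapply(years, function(y) generate_landscape(sim, y)),
    as.character(years)
  )
  base <- landcover[[1]]
  district_map <- generate_district_map(sim, base)
  sites <- generate_apiaries(sim, base)
  organic_polys <- generate_organic_farms(sim, base)
  organic <- build_organic_mask(base, organic_polys)
  tables <- generate_pesticide_tables(sim)

  # --- stage 2: buffers ----------------------------------------------------
  masks <- build_buffer_masks(sites, base, config$radius)
  footprint <- dissolve_buffers(masks)
  bf <- purrr::map_dfr(years, function(y) {
    dplyr::mutate(
      crop_area_in_footprint(footprint, landcover[[as.character(y)]],
        organic, district_map
      ),
      year = y
    )
  })

  # --- stage 3: rates, totals, trends -------------------------------------
  rates <- district_application_rates(tables)
  totals <- total_use_in_buffers(rates, bf, years = years)
  trends <- fit_use_trends(totals, alpha = config$alpha)
  statewide <- statewide_totals(tables)
  statewide_trends <- fit_use_trends(statewide, alpha = config$alpha)

  # --- stage 4: threats and quality per year ------------------------------
  rq <- risk_quotient_table(combine = config$rq_combine)
  rq <- rq[rq$compound %in% config$threat_compounds, , drop = FALSE]
  model <- lapply(years, function(y) {
    threats <- build_threat_layers(
      landcover[[as.character(y)]], organic, district_map,
      rates, y,
      rq_table = rq, compounds = config$compounds
    )
    habitat_quality(landcover[[as.character(y)]], threats,
      k = config$k, z = config$z
    )
  })
  names(model) <- as.character(years)

  # --- stage 5: indices ----------------------------------------------------
  records <- purrr::map_dfr(years, function(y) {
    site_indices(sites, landcover[[as.character(y)]],
      model[[as.character(y)]]$Q, y,
      radius = config$radius, masks = masks
    )
  })
  summary <- summarize_indices(records, reference_year = min(years))
  delta <- site_delta_map(records, min(years), max(years), sites = sites)

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = sim$seed,
    constants = list(
      radius = config$radius, qi_denominator = config$qi_denominator,
      d_max = config$d_max, k = config$k, z = config$z,
      alpha = config$alpha, rq_combine = config$rq_combine
    ),
    years = years,
    n_sites = nrow(sites),
    grid = c(sim$grid_rows, sim$grid_cols),
    footprint_pixels = attr(footprint, "pixel_count"),
    n_use_rows = nrow(tables$use),
    n_index_records = nrow(records)
  )

  result <- list(
    config = config, sites = sites, landcover = landcover,
    district_map = district_map, organic = organic,
    organic_polygons = organic_polys, tables = tables,
    masks = masks, footprint = footprint, bf = bf, rates = rates,
    totals = totals, trends = trends,
    statewide_totals = statewide, statewide_trends = statewide_trends,
    model = model, records = records, summary = summary, delta = delta,
    manifest = manifest
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
  }
  invisible(result)
}

# serialize every pipeline product under out_dir
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$rates, file.path(out_dir, "application_rates.csv"))
  readr::write_csv(result$totals, file.path(out_dir, "buffer_totals.csv"))
  readr::write_csv(result$trends, file.path(out_dir, "trends.csv"))
  readr::write_csv(
    result$statewide_trends,
    file.path(out_dir, "statewide_trends.csv")
  )
  readr::write_csv(result$bf, file.path(out_dir, "buffer_crop_areas.csv"))
  readr::write_csv(result$records, file.path(out_dir, "site_indices.csv"))
  readr::write_csv(result$summary, file.path(out_dir, "index_summary.csv"))
  readr::write_csv(result$delta, file.path(out_dir, "site_delta_qi.csv"))
  for (y in names(result$landcover)) {
    write_asc(result$landcover[[y]], file.path(out_dir, paste0("landcover_", y, ".asc")))
    write_asc(result$model[[y]]$D, file.path(out_dir, paste0("degradation_", y, ".asc")))
    write_asc(result$model[[y]]$Q, file.path(out_dir, paste0("quality_", y, ".asc")))
  }
  sites_geojson <- list(
    type = "FeatureCollection",
    features = purrr::map(seq_len(nrow(result$sites)), function(i) {
      list(
        type = "Feature",
        properties = list(site_id = result$sites$site_id[i]),
        geometry = list(
          type = "Point",
          coordinates = c(result$sites$x[i], result$sites$y[i])
        )
      )
    })
  )
  jsonlite::write_json(sites_geojson, file.path(out_dir, "sites.geojson"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
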