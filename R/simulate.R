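# Synthetic world with known ground truth: patchy land-cover grids,
# multi-year grassland-to-cropland conversion, an apiary registry,
# county-level pesticide-use tables with configured linear trends, and
# organic-farm polygons. Every generator is a pure function of
# (config, year): the same inputs give bit-identical outputs.

#' Simulation configuration
#'
#' Collects every knob of the synthetic world. Defaults emulate the study
#' system: a grassland-dominated mixed agricultural landscape on a 30-m
#' grid, a period of grassland-to-cropland conversion, and county
#' insecticide-use series with linear trends whose slopes match the
#' reported statewide trends (kg/yr).
#'
#' @param seed Integer master seed; all generator randomness derives from it.
#' @param grid_rows,grid_cols Grid dimensions in cells.
#' @param cell_size Cell size in meters (default 30).
#' @param class_proportions Named numeric vector of target class fractions
#'   (names from [class_codes()], must sum to 1).
#' @param patch_scale Smoothing half-width in cells controlling patch size.
#' @param n_sites Number of apiary sites to register.
#' @param min_site_spacing Minimum pairwise site separation in meters.
#' @param years Land-cover/quality assessment years.
#' @param use_years Years covered by the pesticide-use tables.
#' @param conversion_rate Fraction of the initial grassland pixels converted
#'   to cropland per elapsed year, in `[0, 1]`.
#' @param conversion_mode `"patch"` converts whole grassland patches
#'   largest-first (mimicking block conversion of parcels); `"random"`
#'   converts uniformly chosen pixels.
#' @param use_slopes Named vector, statewide use trend slope per compound
#'   (kg/yr).
#' @param use_intercepts Named vector, statewide use in the first use year
#'   (kg).
#' @param use_noise_sd Per-county Gaussian noise sd on use estimates (kg).
#' @param n_districts,n_counties Number of crop reporting districts and of
#'   counties (counties are assigned to districts round-robin).
#' @param crop_ratios Named list: per compound, a named vector of
#'   pesticide-crop use fractions (summing to at most 1 over crops).
#' @param n_organic Number of square organic-farm polygons to place.
#' @param organic_size_m Side length of each organic polygon (meters).
#' @return A validated `simulation_config` list.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, grid_rows = 100, grid_cols = 100)
#' cfg$conversion_rate
simulation_config <- function(seed = 1L,
                              grid_rows = 200L,
                              grid_cols = 200L,
                              cell_size = 30,
                              class_proportions = c(
                                grassland = 0.40, corn = 0.15, soybeans = 0.15,
                                wheat = 0.10, other_crops = 0.06,
                                wetland = 0.08, forest = 0.06
                              ),
                              patch_scale = 5L,
                              n_sites = 10L,
                              min_site_spacing = 500,
                              years = c(2006L, 2010L, 2014L),
                              use_years = 2001:2014,
                              conversion_rate = 0.04,
                              conversion_mode = c("patch", "random"),
                              use_slopes = c(
                                "Chlorpyrifos" = 8867.2,
                                "Clothianidin" = 1329.9,
                                "Thiamethoxam" = 795,
                                "Imidacloprid" = 686.7,
                                "Cyhalothrin-lambda" = 236.4,
                                "Bifenthrin" = 150,
                                "Cyfluthrin" = 50,
                                "Esfenvalerate" = 0
                              ),
                              use_intercepts = c(
                                "Chlorpyrifos" = 6500,
                                "Clothianidin" = 0,
                                "Thiamethoxam" = 100,
                                "Imidacloprid" = 200,
                                "Cyhalothrin-lambda" = 500,
                                "Bifenthrin" = 300,
                                "Cyfluthrin" = 200,
                                "Esfenvalerate" = 400
                              ),
                              use_noise_sd = 300,
                              n_districts = 3L,
                              n_counties = 9L,
                              crop_ratios = NULL,
                              n_organic = 2L,
                              organic_size_m = 150) {
  conversion_mode <- match.arg(conversion_mode)
  known <- setdiff(names(class_codes()), "nodata")
  if (!all(names(class_proportions) %in% known)) {
    stop(
      "unknown land-cover class in `class_proportions`: ",
      paste(setdiff(names(class_proportions), known), collapse = ", "),
      call. = FALSE
    )
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("`class_proportions` must sum to 1", call. = FALSE)
  }
  if (conversion_rate < 0 || conversion_rate > 1) {
    stop("`conversion_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (cell_size <= 0) stop("`cell_size` must be positive", call. = FALSE)
  if (length(use_slopes) == 0) stop("`use_slopes` must be non-empty", call. = FALSE)
  stopifnot(identical(sort(names(use_slopes)), sort(names(use_intercepts))))
  if (is.null(crop_ratios)) {
    crop_ratios <- list(
      "Chlorpyrifos" = c(soybeans = 0.50, wheat = 0.35, corn = 0.15),
      "Clothianidin" = c(corn = 0.90, soybeans = 0.05, wheat = 0.05),
      "Imidacloprid" = c(soybeans = 0.70, corn = 0.20, wheat = 0.10),
      "Thiamethoxam" = c(corn = 0.35, soybeans = 0.35, wheat = 0.30),
      "Cyhalothrin-lambda" = c(soybeans = 0.50, wheat = 0.30, corn = 0.20),
      "Bifenthrin" = c(soybeans = 0.60, corn = 0.30, wheat = 0.10),
      "Cyfluthrin" = c(corn = 0.40, soybeans = 0.40, wheat = 0.20),
      "Esfenvalerate" = c(corn = 0.40, soybeans = 0.30, wheat = 0.30)
    )[names(use_slopes)]
  }
  for (nm in names(crop_ratios)) {
    r <- crop_ratios[[nm]]
    if (any(r < 0) || sum(r) > 1 + 1e-9) {
      stop("crop ratios for ", nm, " must be in [0,1] and sum to at most 1",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      seed = as.integer(seed), grid_rows = as.integer(grid_rows),
      grid_cols = as.integer(grid_cols), cell_size = cell_size,
      class_proportions = class_proportions, patch_scale = as.integer(patch_scale),
      n_sites = as.integer(n_sites), min_site_spacing = min_site_spacing,
      years = as.integer(years), use_years = as.integer(use_years),
      conversion_rate = conversion_rate, conversion_mode = conversion_mode,
      use_slopes = use_slopes, use_intercepts = use_intercepts,
      use_noise_sd = use_noise_sd, n_districts = as.integer(n_districts),
      n_counties = as.integer(n_counties), crop_ratios = crop_ratios,
      n_organic = as.integer(n_organic), organic_size_m = organic_size_m
    ),
    class = "simulation_config"
  )
}

# windowed (box) mean along both axes with edge clamping; two passes give
# an approximately Gaussian smooth with patch size ~ w cells
box_smooth <- function(m, w) {
  if (w <= 1) {
    return(m)
  }
  smooth_cols <- function(a) {
    n <- nrow(a)
    cs <- rbind(0, apply(a, 2, cumsum))
    lo <- pmax(seq_len(n) - w, 0)
    hi <- pmin(seq_len(n) + w, n)
    (cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]) / (hi - lo)
  }
  for (pass in 1:2) {
    m <- smooth_cols(m)
    m <- t(smooth_cols(t(m)))
  }
  m
}

#' Generate a synthetic land-cover grid
#'
#' Builds a patchy categorical landscape by thresholding a smoothed
#' Gaussian random field at the quantiles of the cumulative class
#' proportions, so realized class fractions match the targets up to
#' discretization. For years after the first assessment year, the
#' configured grassland conversion is applied (see
#' [simulate_conversion()]), making the multi-year series internally
#' consistent. Deterministic in `(config, year)`.
#'
#' @param config A [simulation_config()].
#' @param year One of `config$years`.
#' @return A `bee_grid` of analysis class codes.
#' @export
#' @examples
#' cfg <- simulation_config(grid_rows = 80, grid_cols = 80, n_sites = 2)
#' lc <- generate_landscape(cfg, 2006)
#' table(as.vector(lc))
generate_landscape <- function(config, year) {
  stopifnot(inherits(config, "simulation_config"))
  if (!year %in% config$years) {
    stop("`year` must be one of config$years", call. = FALSE)
  }
  props <- config$class_proportions
  base <- withr::with_seed(config$seed, {
    field <- matrix(
      stats::rnorm(config$grid_rows * config$grid_cols),
      config$grid_rows, config$grid_cols
    )
    field <- box_smooth(field, config$patch_scale)
    # rank transform -> exact target fractions up to rounding; ties broken
    # by position for determinism
    r <- rank(as.vector(field), ties.method = "first")
    breaks <- round(cumsum(props) * length(r))
    cls <- findInterval(r, c(0, breaks), left.open = TRUE, rightmost.closed = TRUE)
    codes <- class_codes()[names(props)]
    matrix(as.integer(codes[cls]), config$grid_rows, config$grid_cols)
  })
  grid <- bee_grid(base, cell_size = config$cell_size)
  year_index <- year - min(config$years)
  if (year_index > 0 && config$conversion_rate > 0) {
    grid <- simulate_conversion(grid, config, year_index)
  }
  grid
}

# 4-neighbor connected components of a logical matrix by vectorized label
# propagation (pmin over shifted neighbors until fixpoint)
label_patches <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(as.numeric(seq_along(mask)), nr, nc)
  lab[!mask] <- Inf
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- seq_len(nr)
    cs <- seq_len(nc)
    dest_r <- rs[rs - dr >= 1 & rs - dr <= nr]
    dest_c <- cs[cs - dc >= 1 & cs - dc <= nc]
    out[dest_r, dest_c] <- m[dest_r - dr, dest_c - dc]
    out
  }
  repeat {
    best <- pmin(
      lab,
      shift(lab, 1, 0), shift(lab, -1, 0),
      shift(lab, 0, 1), shift(lab, 0, -1)
    )
    best[!mask] <- Inf
    if (identical(best, lab)) break
    lab <- best
  }
  lab[!mask] <- 0
  lab
}

#' Convert grassland to cropland
#'
#' Reassigns exactly `round(conversion_rate * year_index * n_grassland)`
#' grassland pixels of `base` to crop classes (split across crop classes
#' in proportion to their configured shares). In `"patch"` mode whole
#' grassland patches are converted largest-first, mimicking parcel-scale
#' conversion; `"random"` mode draws pixels uniformly. If the quota
#' exceeds the available grassland, all of it is converted with a warning.
#' No other pixels change. Deterministic in `(config, year_index)`.
#'
#' @param base A land-cover `bee_grid`.
#' @param config A [simulation_config()].
#' @param year_index Non-negative number of elapsed years.
#' @return A `bee_grid` with converted pixels.
#' @export
simulate_conversion <- function(base, config, year_index) {
  stopifnot(inherits(base, "bee_grid"), year_index >= 0)
  codes <- class_codes()
  grass <- unclass(base) == codes[["grassland"]]
  n_grass <- sum(grass)
  n_conv <- round(config$conversion_rate * year_index * n_grass)
  if (n_conv == 0) {
    return(base)
  }
  if (n_conv > n_grass) {
    warning("conversion quota exceeds available grassland; converting all")
    n_conv <- n_grass
  }
  pick <- withr::with_seed(config$seed + 1L, {
    if (config$conversion_mode == "random") {
      sample(which(grass), n_conv)
    } else {
      lab <- label_patches(grass)
      sizes <- sort(table(lab[lab > 0]), decreasing = TRUE)
      chosen <- integer(0)
      for (id in as.integer(names(sizes))) {
        px <- which(lab == id)
        need <- n_conv - length(chosen)
        if (need <= 0) break
        chosen <- c(chosen, px[seq_len(min(need, length(px)))])
      }
      chosen
    }
  })
  # split converted pixels across crop classes by their configured shares
  crop_names <- intersect(
    c("corn", "soybeans", "wheat", "other_crops"),
    names(config$class_proportions)
  )
  shares <- config$class_proportions[crop_names]
  if (length(shares) == 0 || sum(shares) == 0) {
    shares <- c(corn = 1)
    crop_names <- "corn"
  }
  shares <- shares / sum(shares)
  counts <- diff(round(cumsum(c(0, shares)) * length(pick)))
  assign_codes <- rep(codes[crop_names], times = counts)
  out <- unclass(base)
  out[pick] <- as.integer(assign_codes)
  grid_like(base, out)
}

#' Register synthetic apiary sites
#'
#' Places `n_sites` apiary points at cell centers, at least
#' `min_site_spacing` meters apart, preferring locations at least one
#' buffer radius from the grid edge so buffers are not truncated (falls
#' back to the whole extent on small grids). Greedy seeded sampling;
#' errors if the spacing constraint cannot be met.
#'
#' @param config A [simulation_config()].
#' @param landscape A `bee_grid` giving the extent.
#' @param interior_margin Margin from the edges in meters (default the
#'   buffer radius when the grid is large enough).
#' @return A tibble with columns `site_id`, `x`, `y`.
#' @export
generate_apiaries <- function(config, landscape,
                              interior_margin = BUFFER_RADIUS_M) {
  stopifnot(config$n_sites >= 1)
  ext <- grid_extent(landscape)

  try_margin <- function(margin) {
    cx <- cell_center_x(landscape, seq_len(ncol(landscape)))
    cy <- cell_center_y(landscape, seq_len(nrow(landscape)))
    cols <- which(cx >= ext[["xmin"]] + margin & cx <= ext[["xmax"]] - margin)
    rows <- which(cy >= ext[["ymin"]] + margin & cy <= ext[["ymax"]] - margin)
    if (length(cols) == 0 || length(rows) == 0) {
      return(NULL)
    }
    cand <- expand.grid(row = rows, col = cols)
    withr::with_seed(config$seed + 2L, {
      ord <- sample(nrow(cand))
      xs <- cell_center_x(landscape, cand$col[ord])
      ys <- cell_center_y(landscape, cand$row[ord])
      keep_x <- numeric(0)
      keep_y <- numeric(0)
      for (k in seq_along(xs)) {
        if (length(keep_x) == config$n_sites) break
        if (length(keep_x) == 0 ||
          all((xs[k] - keep_x)^2 + (ys[k] - keep_y)^2 >=
            config$min_site_spacing^2)) {
          keep_x <- c(keep_x, xs[k])
          keep_y <- c(keep_y, ys[k])
        }
      }
      if (length(keep_x) < config$n_sites) {
        return(NULL)
      }
      tibble::tibble(
        site_id = sprintf("S%03d", seq_len(config$n_sites)),
        x = keep_x, y = keep_y
      )
    })
  }

  # prefer untruncated buffers (sites one radius from the edge); fall back
  # to the whole extent when the interior cannot host the sites
  sites <- try_margin(interior_margin)
  if (is.null(sites) && interior_margin > 0) {
    sites <- try_margin(0)
  }
  if (is.null(sites)) {
    stop(sprintf(
      "cannot place %d sites with %g m pairwise spacing on this extent",
      config$n_sites, config$min_site_spacing
    ), call. = FALSE)
  }
  sites
}

#' District map and county lookup for the synthetic world
#'
#' Districts are vertical bands of equal width; counties are assigned to
#' districts round-robin, emulating a crop-reporting-district structure at
#' desk scale.
#'
#' @param config A [simulation_config()].
#' @param landscape A `bee_grid` giving the geometry.
#' @return `generate_district_map()`: an integer `bee_grid` of district
#'   ids; `county_district_lookup()`: a tibble `county`, `district`.
#' @export
generate_district_map <- function(config, landscape) {
  nd <- config$n_districts
  band <- ceiling(ncol(landscape) / nd)
  ids <- pmin((seq_len(ncol(landscape)) - 1) %/% band + 1, nd)
  grid_like(landscape, matrix(as.integer(ids),
    nrow(landscape), ncol(landscape),
    byrow = TRUE
  ))
}

#' @rdname generate_district_map
#' @export
county_district_lookup <- function(config) {
  tibble::tibble(
    county = seq_len(config$n_counties),
    district = ((seq_len(config$n_counties) - 1) %% config$n_districts) + 1L
  )
}

#' Generate synthetic pesticide-use tables
#'
#' County-level annual use estimates with a configured statewide linear
#' trend: the statewide total for compound `i` in year `t` is
#' `intercept_i + slope_i * (t - first_year)`, split across counties by
#' fixed seeded shares, with independent Gaussian noise (sd
#' `use_noise_sd`) added per county and truncation at zero. With zero
#' noise the summed county series recovers the configured slope exactly.
#' Also returns the pesticide-crop ratio table, district planted-area
#' table, and the county-district lookup.
#'
#' @param config A [simulation_config()].
#' @return An object of class `pesticide_tables`: a list of tibbles
#'   `use` (county, year, compound, kg), `ratios` (compound, crop, year,
#'   ratio), `areas` (district, crop, year, hectares), and `lookup`
#'   (county, district).
#' @export
#' @examples
#' tabs <- generate_pesticide_tables(simulation_config(use_noise_sd = 0))
#' head(tabs$use)
generate_pesticide_tables <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  compounds <- names(config$use_slopes)
  years <- config$use_years
  t0 <- min(years)
  lookup <- county_district_lookup(config)

  use <- withr::with_seed(config$seed + 3L, {
    shares <- stats::runif(config$n_counties)
    shares <- shares / sum(shares)
    grid <- tidyr::expand_grid(
      compound = compounds, year = years, county = lookup$county
    )
    statewide <- config$use_intercepts[grid$compound] +
      config$use_slopes[grid$compound] * (grid$year - t0)
    noise <- if (config$use_noise_sd > 0) {
      stats::rnorm(nrow(grid), 0, config$use_noise_sd)
    } else {
      0
    }
    grid$kg <- pmax(statewide * shares[grid$county] + noise, 0)
    grid[, c("county", "year", "compound", "kg")]
  })

  ratios <- purrr::map_dfr(compounds, function(cp) {
    r <- config$crop_ratios[[cp]]
    tidyr::expand_grid(
      compound = cp, crop = names(r), year = years
    ) |> dplyr::mutate(ratio = unname(r[.data$crop]))
  })

  # constant planted areas (ha) with mild deterministic district variation
  base_area <- c(corn = 20000, soybeans = 30000, wheat = 28000, other_crops = 10000)
  areas <- tidyr::expand_grid(
    district = seq_len(config$n_districts),
    crop = names(base_area), year = years
  ) |>
    dplyr::mutate(hectares = unname(base_area[.data$crop]) *
      (0.85 + 0.1 * .data$district))

  structure(
    list(use = use, ratios = ratios, areas = areas, lookup = lookup),
    class = "pesticide_tables"
  )
}

#' Generate organic-farm polygons
#'
#' Places square organic-farm polygons centered on cropland pixels
#' (seeded, deterministic). Returned polygons are closed rings in the
#' grid's local CRS.
#'
#' @param config A [simulation_config()].
#' @param landscape A land-cover `bee_grid`.
#' @return A list of tibbles with columns `x`, `y` (possibly empty).
#' @export
generate_organic_farms <- function(config, landscape) {
  if (config$n_organic == 0) {
    return(list())
  }
  codes <- class_codes()
  cropland <- which(unclass(landscape) %in% codes[c("corn", "soybeans", "wheat", "other_crops")])
  if (length(cropland) == 0) {
    return(list())
  }
  half <- config$organic_size_m / 2
  withr::with_seed(config$seed + 4L, {
    centers <- sample(cropland, min(config$n_organic, length(cropland)))
    purrr::map(centers, function(k) {
      r <- ((k - 1) %% nrow(landscape)) + 1
      c <- ((k - 1) %/% nrow(landscape)) + 1
      cx <- cell_center_x(landscape, c)
      cy <- cell_center_y(landscape, r)
      tibble::tibble(
        x = cx + c(-half, half, half, -half, -half),
        y = cy + c(-half, -half, half, half, -half)
      )
    })
  })
}
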