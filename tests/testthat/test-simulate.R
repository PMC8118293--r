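# Synthetic-world generators: determinism, target class fractions,
# conversion accounting, site spacing, and trend structure of the use
# tables.

test_that("generated landscapes are deterministic and hit class targets", {
  cfg <- simulation_config(
    seed = 11, grid_rows = 200, grid_cols = 200,
    class_proportions = c(corn = 0.5, grassland = 0.5)
  )
  a <- generate_landscape(cfg, 2006)
  b <- generate_landscape(cfg, 2006)
  expect_identical(unclass(a), unclass(b))
  frac_corn <- mean(unclass(a) == class_codes()[["corn"]])
  expect_gte(frac_corn, 0.45)
  expect_lte(frac_corn, 0.55)
  expect_true(all(unclass(a) %in% class_codes()))

  # degenerate single-class world
  cfg1 <- simulation_config(
    grid_rows = 30, grid_cols = 30,
    class_proportions = c(grassland = 1)
  )
  expect_true(all(unclass(generate_landscape(cfg1, 2006)) ==
    class_codes()[["grassland"]]))
})

test_that("class fractions stay within 5 points of targets for the default mix", {
  cfg <- simulation_config(seed = 3, grid_rows = 200, grid_cols = 200)
  lc <- generate_landscape(cfg, 2006)
  for (cls in names(cfg$class_proportions)) {
    realized <- mean(unclass(lc) == class_codes()[[cls]])
    expect_lt(abs(realized - cfg$class_proportions[[cls]]), 0.05)
  }
})

test_that("unknown classes in proportions are a configuration error", {
  expect_error(
    simulation_config(class_proportions = c(lava = 1)),
    "unknown land-cover class"
  )
  expect_error(
    simulation_config(class_proportions = c(corn = 0.6, grassland = 0.6)),
    "sum to 1"
  )
  expect_error(simulation_config(conversion_rate = 1.5), "conversion_rate")
})

test_that("conversion reassigns exactly the quota of grassland pixels", {
  cfg <- simulation_config(
    seed = 5, grid_rows = 100, grid_cols = 100,
    class_proportions = c(grassland = 0.5, corn = 0.5),
    conversion_rate = 0.1
  )
  base <- generate_landscape(cfg, 2006)
  n_grass <- sum(unclass(base) == class_codes()[["grassland"]])
  expect_equal(n_grass, 5000) # rank thresholding gives exact fractions

  out <- simulate_conversion(base, cfg, 1)
  changed <- which(unclass(out) != unclass(base))
  expect_length(changed, round(0.1 * 1 * n_grass))
  # only grassland changed, and only into crop codes
  expect_true(all(unclass(base)[changed] == class_codes()[["grassland"]]))
  expect_true(all(unclass(out)[changed] %in% crop_codes()))

  # rate 0 is the identity; quota beyond available converts all with warning
  expect_identical(unclass(simulate_conversion(base, cfg, 0)), unclass(base))
  cfg_all <- simulation_config(
    seed = 5, grid_rows = 100, grid_cols = 100,
    class_proportions = c(grassland = 0.5, corn = 0.5), conversion_rate = 1
  )
  all_gone <- simulate_conversion(base, cfg_all, 1)
  expect_equal(sum(unclass(all_gone) == class_codes()[["grassland"]]), 0)
  expect_warning(
    simulate_conversion(base, cfg_all, 2),
    "exceeds available grassland"
  )
})

test_that("patch-mode conversion consumes whole patches largest-first", {
  # hand-built world: one 6x6 grassland patch and one 2x2 patch in corn
  m <- matrix(class_codes()[["corn"]], 20, 20)
  m[3:8, 3:8] <- class_codes()[["grassland"]]
  m[15:16, 15:16] <- class_codes()[["grassland"]]
  base <- bee_grid(matrix(as.integer(m), 20, 20))
  cfg <- simulation_config(
    grid_rows = 20, grid_cols = 20,
    class_proportions = c(grassland = 0.5, corn = 0.5),
    conversion_rate = 0.9, conversion_mode = "patch"
  )
  # quota = round(0.9 * 40) = 36 = the whole large patch: small one survives
  out <- simulate_conversion(base, cfg, 1)
  expect_equal(sum(unclass(out)[3:8, 3:8] == class_codes()[["grassland"]]), 0)
  expect_equal(sum(unclass(out)[15:16, 15:16] == class_codes()[["grassland"]]), 4)
})

test_that("apiary registry respects extent, spacing, and determinism", {
  cfg <- simulation_config(
    seed = 9, grid_rows = 334, grid_cols = 334,
    n_sites = 4, min_site_spacing = 3500
  )
  lc <- const_grid(176, 334, 334)
  sites <- generate_apiaries(cfg, lc, interior_margin = 0)
  expect_equal(nrow(sites), 4)
  d <- as.matrix(stats::dist(sites[, c("x", "y")]))
  expect_true(all(d[upper.tri(d)] >= 3500))
  ext <- c(0, 334 * 30)
  expect_true(all(sites$x > ext[1] & sites$x < ext[2]))
  expect_identical(sites, generate_apiaries(cfg, lc, interior_margin = 0))

  # single site, and spacing 0 giving exactly n sites
  cfg1 <- simulation_config(n_sites = 1, grid_rows = 40, grid_cols = 40)
  expect_equal(nrow(generate_apiaries(cfg1, const_grid(176, 40, 40))), 1)
  cfg0 <- simulation_config(n_sites = 7, min_site_spacing = 0,
    grid_rows = 40, grid_cols = 40)
  expect_equal(nrow(generate_apiaries(cfg0, const_grid(176, 40, 40))), 7)

  # infeasible spacing names the constraint
  cfg_bad <- simulation_config(
    n_sites = 4, min_site_spacing = 20000,
    grid_rows = 100, grid_cols = 100
  )
  expect_error(
    generate_apiaries(cfg_bad, const_grid(176, 100, 100)),
    "spacing"
  )
})

test_that("pesticide tables carry the configured statewide trend", {
  cfg <- simulation_config(
    use_noise_sd = 0,
    use_slopes = c("Chlorpyrifos" = 5),
    use_intercepts = c("Chlorpyrifos" = 10),
    use_years = 2001:2010
  )
  tabs <- generate_pesticide_tables(cfg)
  totals <- statewide_totals(tabs)
  expect_equal(totals$total_kg, 10 + 5 * (0:9), tolerance = 1e-12)
  expect_true(all(tabs$use$kg >= 0))
  expect_true(all(tabs$areas$hectares > 0))
  # ratios lie in [0,1] and sum to at most 1 over crops
  rsum <- tabs$ratios |>
    dplyr::group_by(compound, year) |>
    dplyr::summarise(s = sum(ratio), .groups = "drop")
  expect_true(all(tabs$ratios$ratio >= 0 & tabs$ratios$ratio <= 1))
  expect_true(all(rsum$s <= 1 + 1e-9))
  # determinism
  expect_identical(tabs$use, generate_pesticide_tables(cfg)$use)
})

test_that("ratio concentrated on one crop leaves the others at zero", {
  cfg <- simulation_config(
    use_slopes = c("Clothianidin" = 100),
    use_intercepts = c("Clothianidin" = 50),
    crop_ratios = list("Clothianidin" = c(corn = 1))
  )
  tabs <- generate_pesticide_tables(cfg)
  expect_setequal(unique(tabs$ratios$crop), "corn")
  rates <- district_application_rates(tabs)
  off_corn <- rates[rates$crop != "corn", ]
  expect_true(all(off_corn$rate_kg_ha == 0))
})

test_that("organic polygons land on cropland and rasterize deterministically", {
  cfg <- simulation_config(seed = 21, grid_rows = 60, grid_cols = 60,
    n_organic = 2)
  lc <- generate_landscape(cfg, 2006)
  polys <- generate_organic_farms(cfg, lc)
  expect_length(polys, 2)
  expect_identical(polys, generate_organic_farms(cfg, lc))
  mask <- build_organic_mask(lc, polys)
  expect_gt(sum(mask), 0)
})
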