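# Site Quality and Degradation Indices and their summaries.

# one interior site on a large single-class grid, plus its mask
interior_site_fixture <- function(code = 176, nr = 200, nc = 200) {
  g <- const_grid(code, nr, nc)
  site <- list(x = 2985, y = -2985, site_id = "s1")
  list(grid = g, site = site, mask = build_buffer_mask(site, g))
}

test_that("analytic landscapes give the expected QI and DI", {
  # all natural, no threats: QI = 1, DI = 0
  fx <- interior_site_fixture(176)
  hq <- habitat_quality(fx$grid, list())
  expect_equal(quality_index(fx$mask, hq$Q), 1, tolerance = 1e-12)
  di <- degradation_index(fx$mask, hq$Q, fx$grid)
  expect_equal(di$di, 0, tolerance = 1e-12)
  expect_equal(di$n_natural, QI_DENOMINATOR)

  # all cropland: QI = 0, DI missing
  fc <- interior_site_fixture(1)
  hqc <- habitat_quality(fc$grid, list())
  expect_equal(quality_index(fc$mask, hqc$Q), 0)
  dic <- degradation_index(fc$mask, hqc$Q, fc$grid)
  expect_true(is.na(dic$di))
  expect_equal(dic$n_natural, 0L)
})

test_that("QI is linear in per-pixel quality with the fixed denominator", {
  fx <- interior_site_fixture(176)
  # half the buffer at Q = 1, half at 0 -> QI = n_half / 9018
  q <- matrix(0, 200, 200)
  on <- which(unclass(fx$mask))
  q[on[seq_len(4509)]] <- 1
  expect_equal(
    quality_index(fx$mask, grid_like_oracle(fx$grid, q)), 4509 / 9018
  )
  # uniform Q = 0.8 on natural pixels -> DI = 0.2
  q2 <- matrix(0.8, 200, 200)
  di <- degradation_index(fx$mask, grid_like_oracle(fx$grid, q2), fx$grid)
  expect_equal(di$di, 0.2, tolerance = 1e-12)
  expect_error(
    quality_index(grid_like_oracle(fx$grid, matrix(FALSE, 200, 200)), fx$grid),
    "empty"
  )
})

test_that("cross-identity links QI, DI and the natural pixel count", {
  # mixed landscape with real threats: for an interior mask of exactly
  # 9018 cells, QI = (n_natural / 9018) * (1 - DI) because crop pixels
  # contribute zero quality
  cfg <- simulation_config(seed = 17, grid_rows = 200, grid_cols = 200)
  lc <- generate_landscape(cfg, 2006)
  th <- make_threat(lc, which(unclass(lc) %in% crop_codes()), intensity = 1)
  hq <- habitat_quality(lc, list(th))
  mask <- build_buffer_mask(list(x = 2985, y = -2985), lc)
  expect_equal(attr(mask, "pixel_count"), QI_DENOMINATOR)
  qi <- quality_index(mask, hq$Q)
  di <- degradation_index(mask, hq$Q, lc)
  expect_equal(qi, (di$n_natural / QI_DENOMINATOR) * (1 - di$di),
    tolerance = 1e-12
  )
})

test_that("removing all threats forces DI = 0 and QI = n_natural/9018", {
  cfg <- simulation_config(seed = 23, grid_rows = 200, grid_cols = 200)
  lc <- generate_landscape(cfg, 2006)
  hq <- habitat_quality(lc, list())
  mask <- build_buffer_mask(list(x = 2985, y = -2985), lc)
  di <- degradation_index(mask, hq$Q, lc)
  expect_equal(di$di, 0, tolerance = 1e-12)
  expect_equal(
    quality_index(mask, hq$Q), di$n_natural / QI_DENOMINATOR,
    tolerance = 1e-12
  )
})

test_that("summaries reproduce percent-change arithmetic and CI forms", {
  # engineer records whose yearly means equal the printed values
  recs <- tibble::tibble(
    site_id = rep(c("a", "b"), times = 2),
    year = rep(c(2006L, 2014L), each = 2),
    qi = c(0.485 - 0.01, 0.485 + 0.01, 0.428 - 0.01, 0.428 + 0.01),
    di = c(0.0973 - 0.001, 0.0973 + 0.001, 0.19 - 0.001, 0.19 + 0.001)
  )
  s <- summarize_indices(recs, reference_year = 2006)
  qi14 <- s[s$index == "qi" & s$year == 2014, ]
  di14 <- s[s$index == "di" & s$year == 2014, ]
  expect_equal(qi14$pct_change, (0.428 - 0.485) / 0.485 * 100, tolerance = 1e-9)
  expect_equal(round(-qi14$pct_change, 2), 11.75)
  expect_equal(di14$pct_change, (0.19 - 0.0973) / 0.0973 * 100, tolerance = 1e-9)
  expect_equal(round(di14$pct_change, 1), 95.3)
  # identical means -> 0% change; CI halfwidth is 1.96 sd / sqrt(n)
  flat <- summarize_indices(
    dplyr::mutate(recs, qi = rep(c(0.4, 0.5), 2), di = rep(c(0.1, 0.2), 2))
  )
  expect_true(all(abs(flat$pct_change) < 1e-12))
  expect_equal(
    flat$ci95[flat$index == "qi"][1],
    1.96 * stats::sd(c(0.4, 0.5)) / sqrt(2)
  )
})

test_that("missing DI records are excluded, not zero-filled", {
  recs <- tibble::tibble(
    site_id = c("a", "b", "c"), year = 2006L,
    qi = c(0.5, 0.4, 0.3), di = c(0.2, NA, 0.4)
  )
  expect_message(
    s <- summarize_indices(recs),
    "no natural pixels"
  )
  expect_equal(s$n[s$index == "di"], 2)
  expect_equal(s$mean[s$index == "di"], 0.3)
  expect_equal(s$n[s$index == "qi"], 3)
})

test_that("per-site deltas difference the two years and flag absentees", {
  recs <- tibble::tibble(
    site_id = c("a", "b", "a"), year = c(2006L, 2006L, 2014L),
    qi = c(0.6, 0.5, 0.6 - 10 / 9018), di = 0
  )
  expect_message(
    d <- site_delta_map(recs, 2006, 2014),
    "missing from one"
  )
  expect_equal(nrow(d), 1)
  # converting 10 pixels from Q=1 to Q=0 moves QI by exactly -10/9018
  expect_equal(d$delta_qi, -10 / 9018, tolerance = 1e-12)
})

test_that("unchanged world gives zero deltas; conversion makes them negative", {
  cfg <- simulation_config(
    seed = 31, grid_rows = 150, grid_cols = 150,
    n_sites = 2, min_site_spacing = 200, conversion_rate = 0.1,
    years = c(2006L, 2014L)
  )
  lc06 <- generate_landscape(cfg, 2006)
  lc14 <- generate_landscape(cfg, 2014)
  sites <- generate_apiaries(cfg, lc06, interior_margin = 0)
  hq06 <- habitat_quality(lc06, list())
  r06 <- site_indices(sites, lc06, hq06$Q, 2006)
  same <- site_delta_map(dplyr::bind_rows(
    r06, dplyr::mutate(r06, year = 2014L)
  ), 2006, 2014)
  expect_true(all(same$delta_qi == 0))

  hq14 <- habitat_quality(lc14, list())
  r14 <- site_indices(sites, lc14, hq14$Q, 2014)
  drift <- site_delta_map(dplyr::bind_rows(r06, r14), 2006, 2014, sites = sites)
  expect_true(all(drift$delta_qi <= 0))
  expect_true(all(c("x", "y") %in% names(drift)))
})
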