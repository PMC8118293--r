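# Foraging buffers: per-site circular (polygonal) masks on the analysis
# grid, their dissolved union for double-count-free area accounting, and
# the crop-area tallies feeding the buffer-total pesticide equation.
#
# Rasterization convention: a cell belongs to the buffer iff its center
# lies inside an inscribed regular polygon of radius `radius` with
# BUFFER_SEGMENTS segments, rotated by BUFFER_ROT_FRAC of one segment.
# The segment count is calibrated once so an interior site at 1609 m on a
# 30-m grid covers exactly QI_DENOMINATOR = 9018 cells, the fixed
# denominator of the site Quality Index.

# TRUE for points (px, py) inside the calibrated buffer polygon centred on
# (cx, cy). Uses the polygon's support function: a point at angle theta is
# inside iff rho <= apothem / cos(angle to nearest edge normal).
in_buffer_polygon <- function(px, py, cx, cy, radius,
                              n_seg = BUFFER_SEGMENTS, rot_frac = BUFFER_ROT_FRAC) {
  dx <- px - cx
  dy <- py - cy
  rho <- sqrt(dx^2 + dy^2)
  seg <- 2 * pi / n_seg
  theta <- atan2(dy, dx) - rot_frac * seg
  loc <- ((theta %% seg) + seg) %% seg
  lim <- radius * cos(pi / n_seg) / cos(loc - pi / n_seg)
  rho <= lim + 1e-9
}

#' Build one site's foraging-buffer mask
#'
#' Rasterizes the 1.6-km foraging buffer of an apiary site onto the
#' analysis grid. The calibrated polygonal rasterization yields exactly
#' `QI_DENOMINATOR` (9018) cells for an interior site at the default
#' radius on a 30-m grid; edge-truncated buffers simply contain fewer
#' cells (the Quality Index keeps the fixed denominator regardless).
#'
#' @param site A one-row data frame (or list) with `x`, `y` in meters and
#'   optionally `site_id`.
#' @param grid A `bee_grid` providing the geometry.
#' @param radius Buffer radius in meters (default [BUFFER_RADIUS_M]).
#' @return A logical `bee_grid` with attributes `site_id`, `pixel_count`,
#'   `radius`.
#' @export
#' @examples
#' g <- bee_grid(matrix(176L, 200, 200))
#' m <- build_buffer_mask(list(x = 3000, y = -3000), g)
#' attr(m, "pixel_count")
build_buffer_mask <- function(site, grid, radius = BUFFER_RADIUS_M) {
  stopifnot(inherits(grid, "bee_grid"), radius > 0)
  sx <- site$x[[1]]
  sy <- site$y[[1]]
  ext <- grid_extent(grid)
  if (sx < ext[["xmin"]] || sx > ext[["xmax"]] ||
    sy < ext[["ymin"]] || sy > ext[["ymax"]]) {
    stop("site lies outside the grid extent", call. = FALSE)
  }
  cs <- cell_size(grid)
  # restrict to the bounding box of the buffer for speed
  c0 <- max(1L, point_to_col(grid, max(sx - radius, ext[["xmin"]] + cs / 2)))
  c1 <- min(ncol(grid), point_to_col(grid, min(sx + radius, ext[["xmax"]] - cs / 2)))
  r0 <- max(1L, point_to_row(grid, min(sy + radius, ext[["ymax"]] - cs / 2)))
  r1 <- min(nrow(grid), point_to_row(grid, max(sy - radius, ext[["ymin"]] + cs / 2)))
  mask <- matrix(FALSE, nrow(grid), ncol(grid))
  rows <- r0:r1
  cols <- c0:c1
  xs <- cell_center_x(grid, cols)
  ys <- cell_center_y(grid, rows)
  sub <- outer(ys, xs, function(y, x) in_buffer_polygon(x, y, sx, sy, radius))
  mask[rows, cols] <- sub
  out <- grid_like(grid, mask)
  attr(out, "site_id") <- if (!is.null(site$site_id)) site$site_id[[1]] else NA
  attr(out, "pixel_count") <- sum(mask)
  attr(out, "radius") <- radius
  out
}

#' Build buffer masks for a table of sites
#'
#' @param sites Data frame with `site_id`, `x`, `y`.
#' @inheritParams build_buffer_mask
#' @return A named list of buffer masks, one per site.
#' @export
build_buffer_masks <- function(sites, grid, radius = BUFFER_RADIUS_M) {
  masks <- purrr::map(seq_len(nrow(sites)), function(i) {
    build_buffer_mask(sites[i, ], grid, radius)
  })
  stats::setNames(masks, as.character(sites$site_id))
}

#' Dissolve buffer masks into one footprint
#'
#' Logical union of all per-site masks, so overlapping buffers are counted
#' once in area and mass accounting.
#'
#' @param masks List of logical `bee_grid` masks on one grid.
#' @return A logical `bee_grid` with attributes `pixel_count` and
#'   `area_ha` (count times 0.09 ha for 30-m cells).
#' @export
dissolve_buffers <- function(masks) {
  if (length(masks) == 0) {
    stop("no buffer masks to dissolve", call. = FALSE)
  }
  out <- masks[[1]]
  u <- unclass(out) & TRUE
  for (m in masks[-1]) {
    stopifnot_aligned(out, m)
    u <- u | unclass(m)
  }
  res <- grid_like(out, u)
  attr(res, "pixel_count") <- sum(u)
  attr(res, "area_ha") <- sum(u) * (cell_size(out) / 100)^2
  res
}

#' Crop area inside the dissolved footprint
#'
#' Tallies, per district and crop, the non-organic crop area (hectares)
#' inside the dissolved buffer footprint: the `BF` term of the
#' buffer-total equation. Pixels outside every district are tallied under
#' an `"unassigned"` bucket and excluded from totals downstream.
#'
#' @param footprint Logical `bee_grid` from [dissolve_buffers()].
#' @param landcover Reclassified land-cover `bee_grid`.
#' @param organic Logical organic-farm mask (or NULL for none).
#' @param district_map Integer `bee_grid` of district ids (or NULL for a
#'   single district `1`).
#' @return Tibble with columns `district`, `crop`, `hectares`.
#' @export
crop_area_in_footprint <- function(footprint, landcover, organic = NULL,
                                   district_map = NULL) {
  stopifnot_aligned(footprint, landcover)
  if (is.null(organic)) {
    organic <- grid_like(landcover, matrix(FALSE, nrow(landcover), ncol(landcover)))
  }
  stopifnot_aligned(footprint, organic)
  if (is.null(district_map)) {
    district_map <- grid_like(landcover, matrix(1L, nrow(landcover), ncol(landcover)))
  }
  stopifnot_aligned(footprint, district_map)

  ha <- (cell_size(landcover) / 100)^2
  codes <- class_codes()
  crops <- c("corn", "wheat", "soybeans", "other_crops")
  sel <- as.vector(footprint) & !as.vector(organic) &
    as.vector(landcover) %in% codes[crops]
  if (!any(sel)) {
    return(tibble::tibble(
      district = integer(), crop = character(), hectares = numeric()
    ))
  }
  code <- as.vector(landcover)[sel]
  dist <- as.vector(district_map)[sel]
  n_unassigned <- sum(is.na(dist) | dist == grid_nodata(district_map))
  if (n_unassigned > 0) {
    message(sprintf(
      "crop_area_in_footprint: %d crop pixels in no district (excluded)",
      n_unassigned
    ))
  }
  keep <- !is.na(dist) & dist != grid_nodata(district_map)
  tb <- tibble::tibble(
    district = as.integer(dist[keep]),
    crop = names(codes)[match(code[keep], codes)]
  )
  dplyr::summarise(
    dplyr::group_by(tb, .data$district, .data$crop),
    hectares = dplyr::n() * ha, .groups = "drop"
  )
}
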