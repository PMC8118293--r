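# Land-cover preparation: reclassification to the eight analysis classes,
# categorical resampling to the 30-m analysis grid, and masking of organic
# farms (assumed not to receive the insecticides of interest).

#' Build a reclassification table
#'
#' Maps raw land-cover codes (CDL-style) onto the eight analysis codes of
#' [class_codes()]. Codes absent from the table resolve to the nodata code
#' -999.
#'
#' @param mapping A data frame with columns `from` (raw integer code) and
#'   `to` (target code, one of [class_codes()]).
#' @return A `reclass_table` tibble.
#' @export
#' @examples
#' reclass_table(data.frame(from = c(1, 23, 24), to = c(1, 3, 3)))
reclass_table <- function(mapping) {
  mapping <- tibble::as_tibble(mapping)
  stopifnot(all(c("from", "to") %in% names(mapping)))
  if (!all(mapping$to %in% class_codes())) {
    bad <- setdiff(unique(mapping$to), class_codes())
    stop(
      "reclass targets must be analysis codes; offending: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(mapping$from)) {
    stop("duplicate `from` codes in reclass table", call. = FALSE)
  }
  structure(mapping[c("from", "to")], class = c("reclass_table", class(mapping)))
}

#' Default CDL-style reclassification
#'
#' Identity on the eight analysis codes plus the common CDL wheat
#' subclasses (spring 23, winter 24, durum 22) collapsed to the single
#' wheat class, and a representative set of other-crop codes mapped to the
#' "other crops" catch-all. Anything else becomes nodata.
#'
#' @return A `reclass_table`.
#' @export
default_reclass_table <- function() {
  codes <- class_codes()
  reclass_table(tibble::tibble(
    from = c(
      unname(codes),
      22, 23, 24, # durum / spring / winter wheat -> wheat
      21, 27, 28, 31, 36, 41, 42, 43, 53 # barley, canola, oats, sunflower, alfalfa, beets, ...
    ),
    to = c(
      unname(codes),
      rep(codes[["wheat"]], 3),
      rep(codes[["other_crops"]], 9)
    )
  ))
}

#' Reclassify a raw land-cover grid
#'
#' Every output code is one of the eight analysis codes; unmapped input
#' codes become nodata (-999) and their count is reported as the
#' `n_unmapped` attribute (and a message when nonzero). Cell counts are
#' conserved: the output histogram is the pushforward of the input
#' histogram through the table.
#'
#' @param raw A `bee_grid` of integer codes.
#' @param table A [reclass_table()]; defaults to [default_reclass_table()].
#' @param quiet Suppress the unmapped-code message.
#' @return A `bee_grid` on the analysis codes, with attribute `n_unmapped`.
#' @export
reclassify <- function(raw, table = default_reclass_table(), quiet = FALSE) {
  stopifnot(inherits(raw, "bee_grid"))
  lut_from <- table$from
  lut_to <- table$to
  idx <- match(as.vector(raw), lut_from)
  out <- ifelse(is.na(idx), class_codes()[["nodata"]], lut_to[idx])
  n_unmapped <- sum(is.na(idx) & as.vector(raw) != grid_nodata(raw))
  if (n_unmapped > 0 && !quiet) {
    message(sprintf("reclassify: %d cells had unmapped codes -> -999", n_unmapped))
  }
  res <- grid_like(raw, matrix(as.integer(out), nrow(raw), ncol(raw)))
  attr(res, "n_unmapped") <- n_unmapped
  res
}

#' Resample a categorical grid to 30-m resolution
#'
#' Nearest-neighbor on cell centers: each 30-m output cell takes the value
#' of the input cell containing its center. No interpolation, so no class
#' codes are invented; a constant grid stays constant and a 30-m input is
#' returned unchanged.
#'
#' @param grid A `bee_grid` at any resolution.
#' @param target Target cell size in meters (default 30).
#' @return A `bee_grid` at the target resolution covering the same extent
#'   (extent rounded out to a whole number of target cells).
#' @export
resample_to_30m <- function(grid, target = 30) {
  stopifnot(inherits(grid, "bee_grid"))
  if (!is.numeric(target) || target <= 0) {
    stop("target resolution must be positive", call. = FALSE)
  }
  if (isTRUE(all.equal(cell_size(grid), target))) {
    return(grid)
  }
  ext <- grid_extent(grid)
  nc_out <- max(1L, round((ext[["xmax"]] - ext[["xmin"]]) / target))
  nr_out <- max(1L, round((ext[["ymax"]] - ext[["ymin"]]) / target))
  # input row/col under each output cell center
  xs <- ext[["xmin"]] + (seq_len(nc_out) - 0.5) * target
  ys <- ext[["ymax"]] - (seq_len(nr_out) - 0.5) * target
  src_col <- pmin(pmax(floor((xs - origin(grid)[1]) / cell_size(grid)) + 1, 1), ncol(grid))
  src_row <- pmin(pmax(floor((origin(grid)[2] - ys) / cell_size(grid)) + 1, 1), nrow(grid))
  out <- unclass(grid)[src_row, src_col, drop = FALSE]
  bee_grid(out, cell_size = target, origin = origin(grid), nodata = grid_nodata(grid))
}

#' Build an organic-farm mask
#'
#' A logical grid aligned to `grid`, TRUE where the cell center lies inside
#' any organic-farm polygon. Organic fields are exempt from the modelled
#' insecticide applications (excluded from buffer crop areas and threat
#' rasters) but remain cropland for habitat scoring.
#'
#' @param grid A `bee_grid` providing the geometry.
#' @param polygons A list of polygons, each a data frame / matrix with
#'   columns `x`, `y` (meters, same local CRS as the grid). An empty list
#'   gives an all-FALSE mask.
#' @return A logical `bee_grid`.
#' @export
build_organic_mask <- function(grid, polygons = list()) {
  stopifnot(inherits(grid, "bee_grid"))
  mask <- matrix(FALSE, nrow(grid), ncol(grid))
  if (length(polygons) == 0) {
    return(grid_like(grid, mask))
  }
  idx <- expand.grid(row = seq_len(nrow(grid)), col = seq_len(ncol(grid)))
  pts <- cbind(cell_center_x(grid, idx$col), cell_center_y(grid, idx$row))
  inside <- rep(FALSE, nrow(pts))
  for (poly in polygons) {
    poly <- as.matrix(as.data.frame(poly)[, c("x", "y")])
    inside <- inside | mgcv::in.out(poly, pts)
  }
  mask[cbind(idx$row, idx$col)] <- inside
  grid_like(grid, mask)
}
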