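# bee_grid: a minimal single-band raster container. A numeric matrix with a
# cell size (m), an origin at the upper-left corner of the upper-left cell
# in a local projected CRS, and a nodata code. Row 1 is the top of the map;
# x increases with column, y decreases with row. All distances Euclidean
# meters. Membership of a cell in any region is always decided by its
# center point.

#' Construct a grid (single-band raster)
#'
#' @param values Numeric or integer matrix; row 1 is the northern edge.
#' @param cell_size Cell edge length in meters (default 30).
#' @param origin Length-2 numeric `(x, y)` of the upper-left corner of the
#'   grid in a local projected CRS (meters).
#' @param nodata Value treated as missing (default -999).
#' @return A `bee_grid` object.
#' @export
#' @examples
#' g <- bee_grid(matrix(176L, 10, 10))
#' dim(g)
bee_grid <- function(values, cell_size = 30, origin = c(0, 0), nodata = -999) {
  stopifnot(is.matrix(values), is.numeric(values) || is.logical(values))
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("`cell_size` must be a single positive number of meters", call. = FALSE)
  }
  structure(
    values,
    cell_size = as.numeric(cell_size),
    origin = as.numeric(origin),
    nodata = nodata,
    class = c("bee_grid", class(values))
  )
}

#' @export
print.bee_grid <- function(x, ...) {
  cat(sprintf(
    "<bee_grid> %d x %d cells, %g m resolution, origin (%g, %g)\n",
    nrow(x), ncol(x), cell_size(x), origin(x)[1], origin(x)[2]
  ))
  vals <- as.vector(x)
  vals <- vals[vals != grid_nodata(x)]
  if (length(vals)) {
    cat(sprintf(
      "  values: %s\n",
      paste(utils::head(sort(unique(vals)), 10), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Grid metadata accessors
#' @param x A `bee_grid`.
#' @return `cell_size()`: meters per cell edge; `origin()`: upper-left
#'   corner `(x, y)`; `grid_nodata()`: the nodata code.
#' @export
cell_size <- function(x) attr(x, "cell_size")

#' @rdname cell_size
#' @export
origin <- function(x) attr(x, "origin")

#' @rdname cell_size
#' @export
grid_nodata <- function(x) attr(x, "nodata")

# preserve grid geometry while replacing the values
grid_like <- function(template, values) {
  bee_grid(values,
    cell_size = cell_size(template), origin = origin(template),
    nodata = grid_nodata(template)
  )
}

# x/y coordinates (m) of cell centers for given row/col indices
cell_center_x <- function(grid, col) origin(grid)[1] + (col - 0.5) * cell_size(grid)
cell_center_y <- function(grid, row) origin(grid)[2] - (row - 0.5) * cell_size(grid)

# col/row containing a point; NA outside the extent
point_to_col <- function(grid, x) {
  j <- floor((x - origin(grid)[1]) / cell_size(grid)) + 1
  ifelse(j >= 1 & j <= ncol(grid), j, NA_integer_)
}
point_to_row <- function(grid, y) {
  i <- floor((origin(grid)[2] - y) / cell_size(grid)) + 1
  ifelse(i >= 1 & i <= nrow(grid), i, NA_integer_)
}

grid_extent <- function(grid) {
  o <- origin(grid)
  c(
    xmin = o[1], xmax = o[1] + ncol(grid) * cell_size(grid),
    ymin = o[2] - nrow(grid) * cell_size(grid), ymax = o[2]
  )
}

stopifnot_aligned <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
    !isTRUE(all.equal(cell_size(a), cell_size(b))) ||
    !isTRUE(all.equal(origin(a), origin(b)))) {
    stop("grids are not aligned (dimensions, cell size and origin must match)",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Convert a grid to a tidy tibble
#'
#' One row per cell with center coordinates, suitable for dplyr/ggplot2
#' work. Nodata cells are kept (value equals the nodata code) so counts are
#' conserved.
#'
#' @param x A `bee_grid`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @export
as_tibble.bee_grid <- function(x, ...) {
  idx <- expand.grid(row = seq_len(nrow(x)), col = seq_len(ncol(x)))
  xs <- cell_center_x(x, idx$col)
  ys <- cell_center_y(x, idx$row)
  vals <- as.vector(unclass(x)[cbind(idx$row, idx$col)])
  tibble::tibble(row = idx$row, col = idx$col, x = xs, y = ys, value = vals)
}

#' Plot a grid with ggplot2
#'
#' Land-cover grids (integer codes) are drawn with a discrete scale named
#' by class; continuous grids (quality, degradation) with a viridis fill.
#'
#' @param object A `bee_grid`.
#' @param discrete Force a discrete scale; default guesses from the values.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bee_grid <- function(object, discrete = NULL, ...) {
  df <- as_tibble.bee_grid(object)
  df <- df[df$value != grid_nodata(object), , drop = FALSE]
  if (is.null(discrete)) {
    discrete <- all(df$value %in% class_codes())
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
  if (discrete) {
    codes <- class_codes()
    lab <- stats::setNames(names(codes), as.character(codes))
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::scale_fill_brewer(
        palette = "Set2", name = "class",
        labels = function(v) lab[v]
      )
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(name = "value", limits = c(0, 1))
  }
}

#' Read and write grids as ESRI ASCII rasters
#'
#' Plain-text raster exchange format (`.asc`): a 6-line header followed by
#' the matrix in row order from the north. Used for all raster outputs so
#' runs are inspectable and diffable.
#'
#' @param grid A `bee_grid`.
#' @param path File path.
#' @return `write_asc()` returns `path` invisibly; `read_asc()` a `bee_grid`.
#' @export
write_asc <- function(grid, path) {
  ext <- grid_extent(grid)
  header <- c(
    sprintf("ncols %d", ncol(grid)),
    sprintf("nrows %d", nrow(grid)),
    sprintf("xllcorner %.10g", ext[["xmin"]]),
    sprintf("yllcorner %.10g", ext[["ymin"]]),
    sprintf("cellsize %.10g", cell_size(grid)),
    sprintf("NODATA_value %.10g", as.numeric(grid_nodata(grid)))
  )
  body <- apply(unclass(grid), 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1))
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- key
  nr <- as.integer(val[["nrows"]])
  nc <- as.integer(val[["ncols"]])
  m <- do.call(rbind, lapply(lines[7:(6 + nr)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  stopifnot(identical(dim(m), c(nr, nc)))
  cs <- val[["cellsize"]]
  bee_grid(m,
    cell_size = cs,
    origin = c(val[["xllcorner"]], val[["yllcorner"]] + nr * cs),
    nodata = val[["nodata_value"]]
  )
}
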