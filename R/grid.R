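#' Georeferenced raster grid
#'
#' `forest_grid` is the raster currency shared by every stage of the pipeline:
#' orthomosaic bands, colour indices, DSM, DEM and CHM are all grids. A grid is
#' a numeric matrix plus an affine georeference in a projected, metre-unit CRS.
#'
#' Coordinate convention (fixed throughout the package): pixel `(row 1, col 1)`
#' is the top-left cell; the map coordinate of a pixel is its **centre**; `x`
#' increases with column, `y` *decreases* with row. `xmin`/`ymax` are the map
#' coordinates of the outer corner of the top-left pixel.
#'
#' Missing data are stored as `NA` in `values`; the `nodata` sentinel (default
#' -9999) is only used on disk when writing GeoTIFF.
#'
#' @param values numeric matrix (rows = image rows, top row first).
#' @param xmin,ymax map coordinates (m) of the top-left corner of the raster.
#' @param pixel_size pixel edge length in metres; either a single number or
#'   `c(px, py)` with both positive.
#' @param crs CRS identifier string, e.g. `"EPSG:32756"`; must refer to a
#'   projected CRS in metres. `NA` marks an unknown CRS.
#' @param nodata sentinel value used when the grid is written to GeoTIFF.
#' @return an object of class `forest_grid`.
#' @examples
#' g <- grid_create(matrix(0, 10, 10), xmin = 0, ymax = 10, pixel_size = 1)
#' pixel_to_map(g, 1, 1)   # centre of the top-left pixel: (0.5, 9.5)
#' @export
grid_create <- function(values, xmin, ymax, pixel_size, crs = "EPSG:32756",
                        nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("grid must have at least one row and one column", call. = FALSE)
  }
  pixel_size <- rep(as.numeric(pixel_size), length.out = 2L)
  if (any(!is.finite(pixel_size)) || any(pixel_size <= 0)) {
    stop("pixel sizes must be positive finite numbers", call. = FALSE)
  }
  bad <- is.infinite(values)
  if (any(bad)) stop("grid values must be finite or NA", call. = FALSE)
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         px = pixel_size[1L], py = pixel_size[2L],
         crs = if (is.na(crs)) NA_character_ else as.character(crs),
         nodata = as.numeric(nodata)),
    class = "forest_grid"
  )
}

#' @export
print.forest_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<forest_grid> %d x %d pixels, %.3g x %.3g m/pixel\n",
              nrow(v), ncol(v), x$px, x$py))
  cat(sprintf("  extent: x [%.2f, %.2f], y [%.2f, %.2f]  crs: %s\n",
              x$xmin, x$xmin + ncol(v) * x$px,
              x$ymax - nrow(v) * x$py, x$ymax,
              if (is.na(x$crs)) "<unknown>" else x$crs))
  ok <- !is.na(v)
  if (any(ok)) {
    cat(sprintf("  values: [%.4g, %.4g], %d NA of %d\n",
                min(v[ok]), max(v[ok]), sum(!ok), length(v)))
  } else {
    cat("  values: all NA\n")
  }
  invisible(x)
}

#' Is an object a forest_grid?
#' @param x object to test.
#' @export
is_grid <- function(x) inherits(x, "forest_grid")

#' Grid dimensions, resolution and extent helpers
#'
#' `grid_gsd()` returns the ground sampling distance (pixel width, m);
#' `grid_extent()` the `c(xmin, ymin, xmax, ymax)` extent in map metres.
#'
#' @param grid a `forest_grid`.
#' @export
grid_gsd <- function(grid) grid$px

#' @rdname grid_gsd
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$xmin, ymin = grid$ymax - nrow(grid$values) * grid$py,
    xmax = grid$xmin + ncol(grid$values) * grid$px, ymax = grid$ymax)
}

#' Convert between pixel indices and map coordinates
#'
#' `pixel_to_map()` returns the map coordinates of pixel centres (1-based
#' `row`, `col`); `map_to_pixel()` returns the 1-based indices of the cell
#' containing a map point. They are mutually inverse on cell indices.
#'
#' @param grid a `forest_grid`.
#' @param row,col 1-based pixel indices (vectorised).
#' @param x,y map coordinates in metres (vectorised).
#' @return `pixel_to_map()`: a two-column matrix `(x, y)`;
#'   `map_to_pixel()`: a two-column integer matrix `(row, col)`.
#' @export
pixel_to_map <- function(grid, row, col) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (any(row < 1L | row > nr | col < 1L | col > nc)) {
    stop("pixel indices out of range", call. = FALSE)
  }
  cbind(x = grid$xmin + (col - 0.5) * grid$px,
        y = grid$ymax - (row - 0.5) * grid$py)
}

#' @rdname pixel_to_map
#' @export
map_to_pixel <- function(grid, x, y) {
  row <- as.integer(floor((grid$ymax - y) / grid$py)) + 1L
  col <- as.integer(floor((x - grid$xmin) / grid$px)) + 1L
  cbind(row = row, col = col)
}

#' Pixel-centre coordinate axes of a grid
#'
#' Returns the x coordinates of all column centres (increasing) and the y
#' coordinates of all row centres (decreasing, top row first).
#'
#' @param grid a `forest_grid`.
#' @return list with numeric vectors `x` and `y`.
#' @keywords internal
grid_axes <- function(grid) {
  list(x = grid$xmin + (seq_len(ncol(grid$values)) - 0.5) * grid$px,
       y = grid$ymax - (seq_len(nrow(grid$values)) - 0.5) * grid$py)
}

#' Do rasters share one common grid?
#'
#' All pipeline stages require their inputs on a single common grid; rasters
#' with different shapes or transforms are rejected rather than resampled.
#'
#' @param ... two or more `forest_grid` objects.
#' @param tol numeric tolerance on the transform parameters (m).
#' @export
grids_aligned <- function(..., tol = 1e-9) {
  gs <- list(...)
  stopifnot(length(gs) >= 2L)
  ref <- gs[[1L]]
  all(vapply(gs[-1L], function(g) {
    identical(dim(g$values), dim(ref$values)) &&
      abs(g$xmin - ref$xmin) <= tol && abs(g$ymax - ref$ymax) <= tol &&
      abs(g$px - ref$px) <= tol && abs(g$py - ref$py) <= tol
  }, logical(1L)))
}

stop_if_misaligned <- function(..., what = "rasters") {
  if (!grids_aligned(...)) {
    stop(what, " are not on a common grid (shape/transform mismatch); ",
         "resampling is deliberately not performed", call. = FALSE)
  }
  invisible(TRUE)
}

#' A grid with the same georeference but new values
#' @param grid template `forest_grid`.
#' @param values replacement matrix (same shape); defaults to all-`NA`.
#' @export
grid_like <- function(grid, values = NULL) {
  if (is.null(values)) {
    values <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  }
  if (!identical(dim(as.matrix(values)), dim(grid$values))) {
    stop("replacement values have a different shape", call. = FALSE)
  }
  grid_create(values, grid$xmin, grid$ymax, c(grid$px, grid$py),
              crs = grid$crs, nodata = grid$nodata)
}

#' Tabular view of a grid
#'
#' Long-format bridge for dplyr/ggplot2 work: one row per pixel with indices,
#' map-centre coordinates and value.
#'
#' @param x a `forest_grid`.
#' @param ... unused.
#' @param drop_na drop NA pixels (default `FALSE`).
#' @return a tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.forest_grid <- function(x, ..., drop_na = FALSE) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  out <- tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    value = as.vector(x$values)
  )
  xy <- pixel_to_map(x, out$row, out$col)
  out$x <- xy[, 1L]; out$y <- xy[, 2L]
  out <- out[, c("row", "col", "x", "y", "value")]
  if (drop_na) out <- out[!is.na(out$value), ]
  out
}

#' Three aligned R, G, B bands of a drone orthomosaic
#'
#' @param red,green,blue aligned `forest_grid`s with non-negative values.
#' @return an object of class `forest_rgb` (list of the three grids).
#' @export
rgb_orthomosaic <- function(red, green, blue) {
  stopifnot(is_grid(red), is_grid(green), is_grid(blue))
  stop_if_misaligned(red, green, blue, what = "RGB bands")
  for (b in list(red, green, blue)) {
    if (any(b$values < 0, na.rm = TRUE)) {
      stop("orthomosaic bands must be non-negative", call. = FALSE)
    }
  }
  structure(list(red = red, green = green, blue = blue), class = "forest_rgb")
}

#' @export
print.forest_rgb <- function(x, ...) {
  cat("<forest_rgb> 3-band orthomosaic\n")
  print(x$red)
  invisible(x)
}

#' @export
is_rgb <- function(x) inherits(x, "forest_rgb")

#' Raster heat-map of a grid
#'
#' @param object a `forest_grid`.
#' @param ... unused.
#' @param max_pixels cap on pixels drawn; larger grids are strided down.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.forest_grid <- function(object, ..., max_pixels = 4e5) {
  stride <- max(1L, ceiling(sqrt(length(object$values) / max_pixels)))
  v <- object$values[seq(1L, nrow(object$values), by = stride),
                     seq(1L, ncol(object$values), by = stride), drop = FALSE]
  g <- grid_create(v, object$xmin, object$ymax,
                   c(object$px * stride, object$py * stride),
                   crs = object$crs, nodata = object$nodata)
  df <- as_tibble.forest_grid(g)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}
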