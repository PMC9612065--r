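# Shared fixtures and independent oracles for the suite.

# Wrap a 0/1 matrix as a forest_mask on a given grid.
make_mask <- function(m, xmin = 0, ymax = nrow(m) * gsd, gsd = 0.1,
                      threshold = 0.5) {
  g <- grid_create(m, xmin = xmin, ymax = ymax, pixel_size = gsd)
  structure(list(grid = g, source_index = "NGBDI", threshold = threshold),
            class = "forest_mask")
}

# Wrap a value matrix as a forest_index.
make_index <- function(m, xmin = 0, ymax = nrow(m) * gsd, gsd = 0.1,
                       name = "NGBDI") {
  g <- grid_create(m, xmin = xmin, ymax = ymax, pixel_size = gsd)
  structure(list(name = name, grid = g), class = "forest_index")
}

# Build a crown_set from a list of ring-lists without going through a mask.
make_crowns <- function(geometries, grid) {
  df <- tibble::tibble(
    id = seq_along(geometries),
    class_label = NA_integer_,
    n_pixels = NA_integer_,
    area_m2 = vapply(geometries, function(r) crown_area(r), numeric(1)),
    geometry = lapply(geometries, function(r) if (is.matrix(r)) list(r) else r)
  )
  out <- structure(df, class = c("crown_set", class(tibble::tibble())))
  attr(out, "crs") <- grid$crs
  attr(out, "gsd") <- grid$px
  out
}

rect_ring <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# Independent ray-casting point-in-polygon (even-odd over all rings,
# boundary treated as inside via a half-open crossing rule). Used only as a
# test oracle; the implementation goes through sp::point.in.polygon.
oracle_in_rings <- function(px, py, rings) {
  inside <- FALSE
  for (ring in rings) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      if ((yi > py) != (yj > py)) {
        xc <- xi + (py - yi) / (yj - yi) * (xj - xi)
        if (px < xc) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

# Brute-force zonal statistics: scan EVERY pixel of the grid.
oracle_zonal <- function(chm, rings) {
  ax_x <- chm$xmin + (seq_len(ncol(chm$values)) - 0.5) * chm$px
  ax_y <- chm$ymax - (seq_len(nrow(chm$values)) - 0.5) * chm$py
  vals <- c()
  for (r in seq_len(nrow(chm$values))) {
    for (cc in seq_len(ncol(chm$values))) {
      if (oracle_in_rings(ax_x[cc], ax_y[r], rings)) {
        v <- chm$values[r, cc]
        if (!is.na(v)) vals <- c(vals, v)
      }
    }
  }
  vals
}

# Brute-force buffer maximum: scan every pixel, Euclidean centre distance.
oracle_buffer_max <- function(chm, x, y, radius) {
  best <- -Inf; n <- 0L
  for (r in seq_len(nrow(chm$values))) {
    cy <- chm$ymax - (r - 0.5) * chm$py
    for (cc in seq_len(ncol(chm$values))) {
      cx <- chm$xmin + (cc - 0.5) * chm$px
      if ((cx - x)^2 + (cy - y)^2 <= radius^2 && !is.na(chm$values[r, cc])) {
        n <- n + 1L
        best <- max(best, chm$values[r, cc])
      }
    }
  }
  list(max = if (n == 0L) NA_real_ else best, n = n)
}

# One small noise-free scene shared across tests (built once per run).
.scene_env <- new.env(parent = emptyenv())
tiny_clean_scene <- function() {
  if (is.null(.scene_env$clean)) {
    .scene_env$clean <- simulate_scene(
      extent = c(0, 0, 40, 40), gsd = 0.1, n_trees = 12,
      height_range = c(8, 16), min_spacing = 6,
      relief_amplitude = 1.5, correlation_length = 15,
      noise_sd = 0, shadow_fraction = 0, grass_fraction = 0.3,
      gnss_sd = 0, height_error_sd = 0, n_field_points = 12, seed = 42)
  }
  .scene_env$clean
}
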