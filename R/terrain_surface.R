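# DEM from random ground points, and the canopy height model CHM = DSM - DEM.
#
# The DSM tops the canopy; bare-ground elevation is only observed where the
# vegetation mask says "ground". Random ground pixels are sampled there, the
# DSM value at those pixels is taken as ground elevation, a DEM is
# interpolated (Delaunay piecewise-linear, nearest-point fill outside the
# hull), and vegetation height is the per-pixel difference.

#' Sample random ground points from the non-vegetation mask
#'
#' Uniform sampling without replacement of mask-0 pixels; point coordinates
#' are pixel centres and elevations are the DSM values there. Sampled pixels
#' where the DSM is nodata are re-drawn (bounded retries). Deterministic for
#' a given seed.
#'
#' @param mask a `forest_mask` (0 = ground).
#' @param dsm a `forest_grid` aligned with the mask.
#' @param n_points number of points (>= 3 for interpolation).
#' @param seed integer RNG seed.
#' @return a `ground_points` object: tibble (`x, y, z, row, col`) with the
#'   seed as an attribute.
#' @export
sample_ground_points <- function(mask, dsm, n_points, seed = 1) {
  stopifnot(inherits(mask, "forest_mask"), is_grid(dsm))
  stop_if_misaligned(mask$grid, dsm, what = "mask and DSM")
  ground_idx <- which(!is.na(mask$grid$values) & mask$grid$values == 0)
  if (length(ground_idx) < n_points) {
    stop("mask has only ", length(ground_idx), " ground pixels; ",
         n_points, " requested", call. = FALSE)
  }
  idx <- local_seed(seed, {
    pick <- sample(ground_idx, n_points)
    for (try in 1:20) {
      bad <- is.na(dsm$values[pick])
      if (!any(bad)) break
      pool <- setdiff(ground_idx, pick)
      pool <- pool[!is.na(dsm$values[pool])]
      if (length(pool) < sum(bad)) {
        stop("not enough ground pixels with valid DSM", call. = FALSE)
      }
      pick[bad] <- sample(pool, sum(bad))
    }
    if (anyNA(dsm$values[pick])) {
      stop("could not find ", n_points, " ground pixels with valid DSM",
           call. = FALSE)
    }
    pick
  })
  rows <- (idx - 1L) %% nrow(dsm$values) + 1L
  cols <- (idx - 1L) %/% nrow(dsm$values) + 1L
  xy <- pixel_to_map(dsm, rows, cols)
  out <- tibble::tibble(x = xy[, 1L], y = xy[, 2L], z = dsm$values[idx],
                        row = rows, col = cols)
  attr(out, "seed") <- seed
  class(out) <- c("ground_points", class(out))
  out
}

#' Interpolate a DEM from scattered ground points
#'
#' Piecewise-linear interpolation on the Delaunay triangulation of the
#' points (exact on planar surfaces); pixels outside the convex hull take the
#' value of the nearest point. Output is aligned to `template`.
#'
#' @param points a `ground_points` tibble (or any data frame with `x, y, z`).
#' @param template a `forest_grid` defining the output grid.
#' @return a `forest_grid` DEM.
#' @export
interpolate_dem <- function(points, template) {
  stopifnot(is_grid(template))
  pts <- tibble::as_tibble(points)[, c("x", "y", "z")]
  if (nrow(pts) < 3L) stop("need at least 3 ground points", call. = FALSE)
  rx <- diff(range(pts$x)); ry <- diff(range(pts$y))
  if (rx == 0 || ry == 0 ||
      abs(stats::cor(pts$x, pts$y)) > 1 - 1e-12) {
    stop("ground points are collinear; cannot triangulate", call. = FALSE)
  }
  ax <- grid_axes(template)
  yo <- rev(ax$y)                               # interp wants increasing axes
  fit <- interp::interp(pts$x, pts$y, pts$z, output = "grid",
                        xo = ax$x, yo = yo, method = "linear",
                        duplicate = "mean")
  z <- t(fit$z[, rev(seq_along(yo)), drop = FALSE])  # back to row-major, top row first
  na_idx <- which(is.na(z))
  if (length(na_idx) > 0L) {
    rows <- (na_idx - 1L) %% nrow(z) + 1L
    cols <- (na_idx - 1L) %/% nrow(z) + 1L
    qx <- ax$x[cols]; qy <- ax$y[rows]
    nn <- vapply(seq_along(qx), function(i) {
      which.min((pts$x - qx[i])^2 + (pts$y - qy[i])^2)
    }, integer(1L))
    z[na_idx] <- pts$z[nn]
  }
  grid_like(template, z)
}

#' Canopy height model from surface and terrain models
#'
#' `CHM = DSM - DEM` per pixel. Negative differences (DEM overshoot over
#' ground) are clamped to zero by default; the number of clamped pixels is
#' recorded in `attr(, "n_clamped")`. Nodata in either input propagates.
#'
#' @param dsm,dem aligned `forest_grid`s.
#' @param clamp_negative clamp negative heights to 0 (default `TRUE`).
#' @return a `forest_grid` CHM.
#' @export
compute_chm <- function(dsm, dem, clamp_negative = TRUE) {
  stopifnot(is_grid(dsm), is_grid(dem))
  stop_if_misaligned(dsm, dem, what = "DSM and DEM")
  z <- dsm$values - dem$values
  n_clamped <- 0L
  if (clamp_negative) {
    neg <- !is.na(z) & z < 0
    n_clamped <- sum(neg)
    z[neg] <- 0
  }
  out <- grid_like(dsm, z)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Build the aligned DSM / DEM / CHM triplet
#'
#' Convenience wrapper: samples ground points, interpolates the DEM and
#' computes the CHM in one call.
#'
#' @param dsm a `forest_grid`.
#' @param mask a cleaned `forest_mask`.
#' @param ground_point_density points per m^2 (default 1/25, i.e. one point
#'   per 5 x 5 m); `n_points` overrides.
#' @param n_points explicit number of ground points.
#' @param seed integer RNG seed.
#' @param clamp_negative see [compute_chm()].
#' @return list with `dsm`, `dem`, `chm` and the `ground_points` used.
#' @export
surface_set <- function(dsm, mask, ground_point_density = 1 / 25,
                        n_points = NULL, seed = 1, clamp_negative = TRUE) {
  if (is.null(n_points)) {
    area <- nrow(dsm$values) * ncol(dsm$values) * dsm$px * dsm$py
    n_points <- max(10L, round(area * ground_point_density))
  }
  gp <- sample_ground_points(mask, dsm, n_points, seed = seed)
  dem <- interpolate_dem(gp, dsm)
  chm <- compute_chm(dsm, dem, clamp_negative = clamp_negative)
  list(dsm = dsm, dem = dem, chm = chm, ground_points = gp)
}

#' Write ground points to CSV
#'
#' Columns `x, y, z`; the sampling seed is recorded in a `#` header comment.
#'
#' @param points a `ground_points` tibble.
#' @param path output CSV path.
#' @export
write_ground_points <- function(points, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ground points; seed = ", attr(points, "seed")), con)
  utils::write.table(tibble::as_tibble(points)[, c("x", "y", "z")], con,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
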