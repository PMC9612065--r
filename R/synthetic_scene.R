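# Synthetic forest scenes.
#
# The generator replaces undeposited drone products (orthomosaic + DSM) and
# field survey with a seeded simulation that has the statistical structure the
# analysis assumes: smooth terrain, paraboloid tree crowns that are greener
# than the ground, directional shadow at crown borders, Gaussian sensor noise,
# and a GNSS-perturbed stem survey restricted to trees of DBH >= 10 cm.

local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Periodic Gaussian smoothing of a matrix via FFT; sigma in pixels.
fft_gaussian_smooth <- function(m, sigma_px) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- pmin(0:(nr - 1L), nr - 0:(nr - 1L))
  dc <- pmin(0:(nc - 1L), nc - 0:(nc - 1L))
  k <- outer(exp(-dr^2 / (2 * sigma_px^2)), exp(-dc^2 / (2 * sigma_px^2)))
  k <- k / sum(k)
  Re(fft(fft(m) * fft(k), inverse = TRUE)) / length(m)
}

#' Generate smooth synthetic terrain
#'
#' Gaussian-smoothed white noise, rescaled so the total elevation range is at
#' most `2 * relief_amplitude`, on top of `base_elevation`. Deterministic for
#' a given seed.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)` in metres.
#' @param pixel_size ground sampling distance (m).
#' @param relief_amplitude maximum absolute deviation from the mean (m).
#' @param correlation_length smoothing length of the relief (m).
#' @param base_elevation mean elevation (m).
#' @param seed integer RNG seed.
#' @param crs CRS tag for the produced grid.
#' @return a `forest_grid` of ground elevations.
#' @export
generate_terrain <- function(extent, pixel_size, relief_amplitude = 3,
                             correlation_length = 30, base_elevation = 500,
                             seed = 1, crs = "EPSG:32756") {
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  if (relief_amplitude < 0) stop("relief_amplitude must be >= 0", call. = FALSE)
  w <- extent[3L] - extent[1L]; h <- extent[4L] - extent[2L]
  if (w <= 0 || h <= 0) stop("extent must have positive area", call. = FALSE)
  nr <- max(1L, round(h / pixel_size)); nc <- max(1L, round(w / pixel_size))
  z <- if (relief_amplitude == 0) {
    matrix(0, nr, nc)
  } else {
    noise <- local_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
    s <- fft_gaussian_smooth(noise, correlation_length / pixel_size)
    s <- s - mean(s)
    m <- max(abs(s))
    if (m > 0) s * (relief_amplitude / m) else s
  }
  grid_create(z + base_elevation, xmin = extent[1L], ymax = extent[4L],
              pixel_size = pixel_size, crs = crs)
}

#' Place trees in a scene
#'
#' Random stem positions with a hard minimum spacing (dart throwing with
#' bounded retries), uniform heights, crown radius proportional to height, a
#' linear height-to-DBH allometry, and round-robin class labels 1..3.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)` (m).
#' @param n_trees number of trees (>= 1).
#' @param height_range `c(min, max)` tree heights (m).
#' @param crown_ratio crown radius per metre of height (default 0.15).
#' @param min_spacing minimum pairwise stem distance (m).
#' @param seed integer RNG seed.
#' @param allom_a DBH (cm) per metre of height (default 2.0; DBH only feeds
#'   the >= 10 cm survey inclusion rule).
#' @param n_classes number of crown classes cycled over (default 3).
#' @param max_tries placement attempts per tree before giving up.
#' @return a `scene_truth` object: list with a `trees` tibble
#'   (`id, x, y, height_m, crown_radius_m, dbh_cm, class_label`), the extent
#'   and the seed.
#' @export
place_trees <- function(extent, n_trees, height_range = c(10, 30),
                        crown_ratio = 0.15, min_spacing = 5, seed = 1,
                        allom_a = 2.0, n_classes = 3L, max_tries = 200L) {
  stopifnot(n_trees >= 1, min_spacing >= 0, crown_ratio > 0,
            height_range[1L] > 0, height_range[2L] >= height_range[1L])
  pos <- local_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(n_trees)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cx <- stats::runif(1, extent[1L], extent[3L])
        cy <- stats::runif(1, extent[2L], extent[4L])
        if (length(xs) == 0L ||
            min((xs - cx)^2 + (ys - cy)^2) >= min_spacing^2) {
          xs <- c(xs, cx); ys <- c(ys, cy); placed <- TRUE; break
        }
      }
      if (!placed) {
        stop("could not place ", n_trees, " trees at min_spacing = ",
             min_spacing, " m after ", max_tries, " tries each", call. = FALSE)
      }
    }
    list(x = xs, y = ys,
         h = stats::runif(n_trees, height_range[1L], height_range[2L]))
  })
  trees <- tibble::tibble(
    id = seq_len(n_trees),
    x = pos$x, y = pos$y,
    height_m = pos$h,
    crown_radius_m = crown_ratio * pos$h,
    dbh_cm = allom_a * pos$h,
    class_label = ((seq_len(n_trees) - 1L) %% n_classes) + 1L
  )
  structure(list(trees = trees, extent = extent, seed = seed,
                 crown_ratio = crown_ratio),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d trees in [%.0f, %.0f] x [%.0f, %.0f] m\n",
              nrow(x$trees), x$extent[1L], x$extent[3L], x$extent[2L],
              x$extent[4L]))
  print(x$trees, n = 5)
  invisible(x)
}

# Indices of pixels within a tree's crown disc, with squared distances.
crown_pixels <- function(grid, tree) {
  ax <- grid_axes(grid)
  rc <- tree$crown_radius_m
  cols <- which(abs(ax$x - tree$x) <= rc)
  rows <- which(abs(ax$y - tree$y) <= rc)
  if (length(rows) == 0L || length(cols) == 0L) return(NULL)
  d2 <- outer((ax$y[rows] - tree$y)^2, (ax$x[cols] - tree$x)^2, `+`)
  keep <- d2 <= rc^2
  if (!any(keep)) return(NULL)
  list(rows = rows, cols = cols, d2 = d2, keep = keep)
}

#' Render a digital surface model from truth
#'
#' Each crown is a paraboloid of revolution over its stem:
#' `z(d) = ground_at_stem + h * (1 - (d / rc)^2)` for `d <= rc`. The DSM is
#' the pixelwise maximum of the terrain and all crown surfaces, so
#' `DSM >= terrain` everywhere and the apex recovers the tree height exactly
#' up to the half-pixel discretisation bound `h * (gsd / (sqrt(2) * rc))^2`.
#'
#' @param terrain ground-elevation `forest_grid`.
#' @param truth a `scene_truth`.
#' @return a `forest_grid` DSM aligned with `terrain`.
#' @export
render_dsm <- function(terrain, truth) {
  stopifnot(is_grid(terrain), inherits(truth, "scene_truth"))
  z <- terrain$values
  for (i in seq_len(nrow(truth$trees))) {
    tr <- truth$trees[i, ]
    cp <- crown_pixels(terrain, tr)
    if (is.null(cp)) next
    ij <- map_to_pixel(terrain, tr$x, tr$y)
    ij[, 1L] <- pmin(pmax(ij[, 1L], 1L), nrow(z))
    ij[, 2L] <- pmin(pmax(ij[, 2L], 1L), ncol(z))
    ground <- terrain$values[ij[1L, 1L], ij[1L, 2L]]
    crown <- ground + tr$height_m * (1 - cp$d2 / tr$crown_radius_m^2)
    sub <- z[cp$rows, cp$cols, drop = FALSE]
    sub[cp$keep] <- pmax(sub[cp$keep], crown[cp$keep])
    z[cp$rows, cp$cols] <- sub
  }
  grid_like(terrain, z)
}

#' Map of which tree's crown surface tops each pixel
#'
#' Truth companion to [render_dsm()]: an integer grid with the id of the tree
#' whose crown surface is highest at each pixel, 0 on open ground. Used to
#' check masks and crown polygons against known footprints.
#'
#' @inheritParams render_dsm
#' @return a `forest_grid` of tree ids (0 = ground).
#' @export
crown_footprints <- function(terrain, truth) {
  z <- terrain$values
  idm <- matrix(0, nrow(z), ncol(z))
  for (i in seq_len(nrow(truth$trees))) {
    tr <- truth$trees[i, ]
    cp <- crown_pixels(terrain, tr)
    if (is.null(cp)) next
    ij <- map_to_pixel(terrain, tr$x, tr$y)
    ij[, 1L] <- pmin(pmax(ij[, 1L], 1L), nrow(z))
    ij[, 2L] <- pmin(pmax(ij[, 2L], 1L), ncol(z))
    ground <- terrain$values[ij[1L, 1L], ij[1L, 2L]]
    crown <- ground + tr$height_m * (1 - cp$d2 / tr$crown_radius_m^2)
    sub <- z[cp$rows, cp$cols, drop = FALSE]
    subid <- idm[cp$rows, cp$cols, drop = FALSE]
    win <- cp$keep & crown > sub
    sub[win] <- crown[win]; subid[win] <- tr$id
    z[cp$rows, cp$cols] <- sub
    idm[cp$rows, cp$cols] <- subid
  }
  grid_like(terrain, idm)
}

#' Default colour means for scene rendering
#'
#' Mean digital numbers (0-255) per surface class. Crown classes are greener
#' than blue (positive green-blue normalised difference); ground, grass and
#' shadow have green <= blue so the green-blue index separates crowns from
#' everything else — the separability the masking stage relies on.
#'
#' @return named list of RGB triplets (`ground`, `grass`, `shadow`, and a
#'   3-row `crown` matrix, one row per crown class).
#' @export
default_colour_params <- function() {
  list(
    ground = c(110, 100, 105),
    grass  = c(120, 110, 115),
    shadow = c(35, 40, 45),
    crown  = rbind(c(60, 110, 50),
                   c(70, 125, 55),
                   c(45, 95, 60))
  )
}

g_frac <- function(rgb) rgb[2L] / sum(rgb)
b_frac <- function(rgb) rgb[3L] / sum(rgb)

check_colour_separability <- function(cp) {
  for (i in seq_len(nrow(cp$crown))) {
    if (g_frac(cp$crown[i, ]) <= b_frac(cp$crown[i, ])) {
      stop("crown class ", i, " colour has green fraction <= blue fraction; ",
           "the green-blue index could not label the scene", call. = FALSE)
    }
  }
  for (nm in c("ground", "grass", "shadow")) {
    if (g_frac(cp[[nm]]) > b_frac(cp[[nm]])) {
      stop(nm, " colour has green fraction > blue fraction; ",
           "the green-blue index could not label the scene", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Render an RGB orthomosaic from truth
#'
#' Crown pixels take their tree's class colour (taller surfaces win where
#' crowns overlap); open ground is a mix of bare-ground and grass patches; a
#' fraction of each crown's southern border pixels is darkened to shadow;
#' Gaussian sensor noise is added per band and clipped at zero. Deterministic
#' for a given seed.
#'
#' @param terrain ground-elevation `forest_grid` (defines the target grid).
#' @param truth a `scene_truth`.
#' @param colour_params see [default_colour_params()]; checked for green-blue
#'   separability before rendering.
#' @param shadow_fraction fraction of each crown's southern border pixels set
#'   to the shadow colour (0-1).
#' @param noise_sd per-band Gaussian noise standard deviation (digital
#'   numbers).
#' @param grass_fraction fraction of open ground rendered as grass patches.
#' @param seed integer RNG seed.
#' @return a `forest_rgb`.
#' @export
render_orthomosaic <- function(terrain, truth,
                               colour_params = default_colour_params(),
                               shadow_fraction = 0.3, noise_sd = 8,
                               grass_fraction = 0.3, seed = 1) {
  stopifnot(is_grid(terrain), inherits(truth, "scene_truth"))
  check_colour_separability(colour_params)
  nr <- nrow(terrain$values); nc <- ncol(terrain$values)
  bands <- local_seed(seed, {
    R <- matrix(colour_params$ground[1L], nr, nc)
    G <- matrix(colour_params$ground[2L], nr, nc)
    B <- matrix(colour_params$ground[3L], nr, nc)
    if (grass_fraction > 0) {
      field <- fft_gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                                   10 / terrain$px)
      grass <- field > stats::quantile(field, 1 - grass_fraction)
      R[grass] <- colour_params$grass[1L]
      G[grass] <- colour_params$grass[2L]
      B[grass] <- colour_params$grass[3L]
    }
    # a pixel shows the crown whose surface tops the DSM there (z-buffer),
    # so colours, DSM and crown footprints agree exactly
    owner <- crown_footprints(terrain, truth)$values
    for (i in seq_len(nrow(truth$trees))) {
      tr <- truth$trees[i, ]
      cp <- crown_pixels(terrain, tr)
      if (is.null(cp)) next
      col3 <- colour_params$crown[tr$class_label, ]
      sel <- cp$keep & owner[cp$rows, cp$cols] == tr$id
      if (!any(sel)) next
      Rs <- R[cp$rows, cp$cols, drop = FALSE]; Rs[sel] <- col3[1L]
      Gs <- G[cp$rows, cp$cols, drop = FALSE]; Gs[sel] <- col3[2L]
      Bs <- B[cp$rows, cp$cols, drop = FALSE]; Bs[sel] <- col3[3L]
      if (shadow_fraction > 0) {
        ax <- grid_axes(terrain)
        south <- matrix(rep(ax$y[cp$rows] < tr$y, length(cp$cols)),
                        length(cp$rows), length(cp$cols))
        border <- sel & south & cp$d2 > (0.7 * tr$crown_radius_m)^2
        idx <- which(border)
        if (length(idx) > 0L) {
          ns <- round(shadow_fraction * length(idx))
          if (ns > 0L) {
            pick <- sample(idx, ns)
            Rs[pick] <- colour_params$shadow[1L]
            Gs[pick] <- colour_params$shadow[2L]
            Bs[pick] <- colour_params$shadow[3L]
          }
        }
      }
      R[cp$rows, cp$cols] <- Rs
      G[cp$rows, cp$cols] <- Gs
      B[cp$rows, cp$cols] <- Bs
    }
    if (noise_sd > 0) {
      R <- pmax(R + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
      G <- pmax(G + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
      B <- pmax(B + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
    }
    list(R = R, G = G, B = B)
  })
  rgb_orthomosaic(grid_like(terrain, bands$R),
                  grid_like(terrain, bands$G),
                  grid_like(terrain, bands$B))
}

#' Simulate a field survey of stem positions and heights
#'
#' Samples trees with DBH >= 10 cm (the survey inclusion rule) without
#' replacement; recorded positions get per-axis Gaussian GNSS error, recorded
#' heights get Gaussian measurement error.
#'
#' @param truth a `scene_truth`.
#' @param gnss_sd GNSS position error SD per axis (m); default 0.10 m.
#' @param height_error_sd height measurement error SD (m).
#' @param n_points number of surveyed trees (default 116).
#' @param seed integer RNG seed.
#' @return a tibble (`id, x, y, height_m, dbh_cm`), one row per field point.
#' @export
simulate_field_survey <- function(truth, gnss_sd = 0.10, height_error_sd = 0.5,
                                  n_points = 116, seed = 1) {
  eligible <- dplyr::filter(truth$trees, .data$dbh_cm >= 10)
  if (n_points > nrow(eligible)) {
    stop("n_points = ", n_points, " exceeds the ", nrow(eligible),
         " trees with DBH >= 10 cm", call. = FALSE)
  }
  local_seed(seed, {
    picked <- eligible[sample.int(nrow(eligible), n_points), ]
    tibble::tibble(
      id = picked$id,
      x = picked$x + stats::rnorm(n_points, 0, gnss_sd),
      y = picked$y + stats::rnorm(n_points, 0, gnss_sd),
      height_m = pmax(picked$height_m +
                        stats::rnorm(n_points, 0, height_error_sd), 0.01),
      dbh_cm = picked$dbh_cm
    )
  })
}

#' Generate a complete synthetic scene
#'
#' One-stop generator: terrain, tree placement, DSM, orthomosaic and field
#' survey, each stage on its own sub-seed derived from `seed` by fixed
#' offsets. The defaults are the package's reference study conditions: a
#' 100 x 100 m stand at 0.10 m GSD, 120 trees of 10-30 m height, 3 m relief,
#' and a 116-point survey with 0.10 m GNSS and 0.5 m height error.
#'
#' @param extent,gsd scene extent (m) and ground sampling distance (m).
#' @param n_trees,height_range,crown_ratio,min_spacing tree placement
#'   parameters, see [place_trees()].
#' @param relief_amplitude,correlation_length,base_elevation terrain
#'   parameters, see [generate_terrain()].
#' @param colour_params,shadow_fraction,noise_sd,grass_fraction rendering
#'   parameters, see [render_orthomosaic()].
#' @param gnss_sd,height_error_sd,n_field_points survey parameters, see
#'   [simulate_field_survey()].
#' @param seed master seed; stages use `seed + 1 .. seed + 4`.
#' @param crs CRS tag for all produced rasters.
#' @return list with `terrain`, `dsm`, `ortho`, `truth`, `survey` and the
#'   resolved parameter list `params`.
#' @export
simulate_scene <- function(extent = c(0, 0, 100, 100), gsd = 0.10,
                           n_trees = 120, height_range = c(10, 30),
                           crown_ratio = 0.15, min_spacing = 5,
                           relief_amplitude = 3, correlation_length = 30,
                           base_elevation = 500,
                           colour_params = default_colour_params(),
                           shadow_fraction = 0.3, noise_sd = 8,
                           grass_fraction = 0.3,
                           gnss_sd = 0.10, height_error_sd = 0.5,
                           n_field_points = 116, seed = 1,
                           crs = "EPSG:32756") {
  terrain <- generate_terrain(extent, gsd, relief_amplitude,
                              correlation_length, base_elevation,
                              seed = seed + 1, crs = crs)
  truth <- place_trees(extent, n_trees, height_range, crown_ratio,
                       min_spacing, seed = seed + 2)
  dsm <- render_dsm(terrain, truth)
  ortho <- render_orthomosaic(terrain, truth, colour_params, shadow_fraction,
                              noise_sd, grass_fraction, seed = seed + 3)
  survey <- simulate_field_survey(truth, gnss_sd, height_error_sd,
                                  n_field_points, seed = seed + 4)
  params <- list(extent = extent, gsd = gsd, n_trees = n_trees,
                 height_range = height_range, crown_ratio = crown_ratio,
                 min_spacing = min_spacing,
                 relief_amplitude = relief_amplitude,
                 correlation_length = correlation_length,
                 base_elevation = base_elevation,
                 shadow_fraction = shadow_fraction, noise_sd = noise_sd,
                 grass_fraction = grass_fraction, gnss_sd = gnss_sd,
                 height_error_sd = height_error_sd,
                 n_field_points = n_field_points, seed = seed, crs = crs)
  list(terrain = terrain, dsm = dsm, ortho = ortho, truth = truth,
       survey = survey, params = params)
}
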