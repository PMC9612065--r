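# Vegetation masking and crown polygon extraction.
#
# An index raster (NGBDI by default) is thresholded into a 0/1 ground/
# vegetation mask, cleaned morphologically, and traced into one simplified
# polygon per 8-connected component. Touching crowns are deliberately NOT
# split: each connected vegetated region is one inventory unit.

#' Threshold an index raster into a vegetation mask
#'
#' `mask = 1` where the index exceeds the threshold, else 0; nodata
#' propagates. With `threshold = "auto"` the threshold is chosen by Otsu's
#' method on a 256-bin histogram over the observed value range — a
#' reproducible stand-in for choosing a break by visual inspection — and the
#' value actually used is recorded on the result.
#'
#' @param index a `forest_index`.
#' @param threshold a number, or `"auto"` for Otsu's method.
#' @return an object of class `forest_mask`: list with `grid` (0/1/NA
#'   values), `source_index`, `threshold`.
#' @export
reclassify_index <- function(index, threshold = "auto") {
  stopifnot(inherits(index, "forest_index"))
  v <- index$grid$values
  ok <- !is.na(v)
  if (identical(threshold, "auto")) {
    vals <- v[ok]
    if (length(unique(vals)) < 2L) {
      stop("cannot auto-threshold a constant raster", call. = FALSE)
    }
    threshold <- otsu_threshold(vals, levels = 256L)
  }
  m <- matrix(NA_real_, nrow(v), ncol(v))
  m[ok] <- as.numeric(v[ok] > threshold)
  structure(list(grid = grid_like(index$grid, m),
                 source_index = index$name, threshold = threshold),
            class = "forest_mask")
}

# Otsu's threshold on a fixed-bin histogram over the observed range.
# EBImage::otsu provides the same statistic but requires [0,1] Image input;
# this maps the values into [0,1], delegates, and maps back.
otsu_threshold <- function(vals, levels = 256L) {
  lo <- min(vals); hi <- max(vals)
  scaled <- (vals - lo) / (hi - lo)
  t01 <- EBImage::otsu(matrix(scaled, nrow = 1L), range = c(0, 1),
                       levels = levels)
  lo + t01 * (hi - lo)
}

#' @export
print.forest_mask <- function(x, ...) {
  v <- x$grid$values
  cat(sprintf("<forest_mask> from %s at threshold %.6g: %d vegetation, %d ground, %d NA\n",
              x$source_index, x$threshold, sum(v == 1, na.rm = TRUE),
              sum(v == 0, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' Morphologically clean a vegetation mask
#'
#' Closing with a disc structuring element (fills pinholes and cracks),
#' then removal of 8-connected vegetation patches smaller than
#' `min_patch_area_m2`. `clean_mask(m, 0, 0)` is the identity.
#'
#' @param mask a `forest_mask`.
#' @param min_patch_area_m2 minimum patch area kept (m^2).
#' @param closing_radius_px disc radius for morphological closing (pixels).
#' @return a cleaned `forest_mask`.
#' @export
clean_mask <- function(mask, min_patch_area_m2 = 1, closing_radius_px = 1L) {
  stopifnot(inherits(mask, "forest_mask"))
  if (min_patch_area_m2 < 0 || closing_radius_px < 0) {
    stop("cleaning parameters must be non-negative", call. = FALSE)
  }
  v <- mask$grid$values
  na <- is.na(v)
  bin <- v
  bin[na] <- 0
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L,
                                shape = "disc")
    bin <- EBImage::closing(bin, brush)
  }
  if (min_patch_area_m2 > 0) {
    lab <- label_components(bin)
    if (max(lab) > 0L) {
      sizes <- tabulate(lab[lab > 0L])
      px_area <- mask$grid$px * mask$grid$py
      drop <- which(sizes * px_area < min_patch_area_m2)
      bin[lab %in% drop] <- 0
    }
  }
  bin[na] <- NA_real_
  structure(list(grid = grid_like(mask$grid, bin),
                 source_index = mask$source_index, threshold = mask$threshold),
            class = "forest_mask")
}

#' 8-connected component labels of a binary matrix
#'
#' `EBImage::bwlabel()` labels with 4-connectivity; crowns touching
#' diagonally must be one unit, so labels that touch diagonally are merged
#' through the label adjacency graph.
#'
#' @param bin numeric/logical matrix, non-zero = foreground (NA = background).
#' @return integer matrix of labels (0 = background), relabelled 1..n in
#'   (top-most, then left-most) component-pixel order.
#' @export
label_components <- function(bin) {
  bin <- as.matrix(bin)
  bin[is.na(bin)] <- 0
  lab <- EBImage::bwlabel(bin != 0)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nlab <- max(lab)
  if (nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a <- lab[-nr, -nc]; b <- lab[-1L, -1L]   # down-right diagonal pairs
    c_ <- lab[-nr, -1L]; d <- lab[-1L, -nc]  # down-left diagonal pairs
    s1 <- a > 0L & b > 0L & a != b
    s2 <- c_ > 0L & d > 0L & c_ != d
    pairs <- unique(rbind(cbind(a[s1], b[s1]), cbind(c_[s2], d[s2])))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (p in seq_len(nrow(pairs))) {
        ra <- find(pairs[p, 1L]); rb <- find(pairs[p, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(nlab), find, integer(1L))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  relabel_by_position(lab)
}

# Relabel components 1..n ordered by (min row, then min col at that row).
relabel_by_position <- function(lab) {
  nlab <- max(lab)
  if (nlab == 0L) return(lab)
  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  labs <- lab[idx]
  ord <- order(labs, rows, cols)
  first <- ord[!duplicated(labs[ord])]        # top-most/left-most pixel per label
  rank <- order(order(rows[first], cols[first]))
  remap <- integer(nlab)
  remap[labs[first]] <- rank
  lab[idx] <- remap[labs]
  lab
}

# ---- boundary tracing -------------------------------------------------------

# Trace the boundary rings of one component (logical bbox matrix `m`,
# offset by (row0, col0) pixels). Corners live on the pixel lattice; edges
# are directed so the exterior ring has positive shoelace area in map
# coordinates. At pinch corners (diagonal touch) the leftmost turn is taken,
# keeping an 8-connected component a single outer ring.
trace_rings_px <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  idx <- which(m)
  r <- (idx - 1L) %% nr + 1L
  c_ <- (idx - 1L) %/% nr + 1L
  # neighbour presence via padded lookup
  up    <- pad[cbind(r,     c_ + 1L)]
  down  <- pad[cbind(r + 2L, c_ + 1L)]
  left  <- pad[cbind(r + 1L, c_)]
  right <- pad[cbind(r + 1L, c_ + 2L)]
  # directed edges between corners (c, r) with 0-based lattice coords
  e_from <- list(); e_to <- list()
  add <- function(fc, fr, tc, tr) {
    e_from[[length(e_from) + 1L]] <<- cbind(fc, fr)
    e_to[[length(e_to) + 1L]] <<- cbind(tc, tr)
  }
  if (any(!up))    add(c_[!up] - 1L,    r[!up] - 1L,    c_[!up],          r[!up] - 1L)
  if (any(!right)) add(c_[!right],     r[!right] - 1L, c_[!right],       r[!right])
  if (any(!down))  add(c_[!down],      r[!down],       c_[!down] - 1L,   r[!down])
  if (any(!left))  add(c_[!left] - 1L, r[!left],       c_[!left] - 1L,   r[!left] - 1L)
  from <- do.call(rbind, e_from); to <- do.call(rbind, e_to)
  ne <- nrow(from)
  key <- function(cc, rr) cc * (nr + 2L) + rr
  from_key <- key(from[, 1L], from[, 2L])
  out_by_corner <- split(seq_len(ne), from_key)
  used <- logical(ne)
  rings <- list()
  for (start in seq_len(ne)) {
    if (used[start]) next
    ring <- list()
    e <- start
    repeat {
      used[e] <- TRUE
      ring[[length(ring) + 1L]] <- from[e, ]
      nxt_key <- as.character(key(to[e, 1L], to[e, 2L]))
      cand <- out_by_corner[[nxt_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      if (length(cand) == 1L) {
        e <- cand
      } else {
        din <- to[e, ] - from[e, ]
        # leftmost turn first: cross product (screen y-down) == -1
        turn <- vapply(cand, function(j) {
          dout <- to[j, ] - from[j, ]
          din[1L] * dout[2L] - din[2L] * dout[1L]
        }, numeric(1L))
        e <- cand[order(turn)][1L]
      }
    }
    rings[[length(rings) + 1L]] <- do.call(rbind, ring)
  }
  rings
}

# Drop collinear runs from a closed ring (n x 2 matrix, no repeated endpoint).
drop_collinear <- function(ring) {
  n <- nrow(ring)
  if (n < 4L) return(ring)
  prev <- ring[c(n, 1:(n - 1L)), , drop = FALSE]
  nxt <- ring[c(2:n, 1L), , drop = FALSE]
  cross <- (ring[, 1L] - prev[, 1L]) * (nxt[, 2L] - ring[, 2L]) -
           (ring[, 2L] - prev[, 2L]) * (nxt[, 1L] - ring[, 1L])
  keep <- abs(cross) > 1e-12
  if (!any(keep)) keep[1:2] <- TRUE
  ring[keep, , drop = FALSE]
}

# Douglas-Peucker simplification of a closed ring with tolerance tol.
simplify_ring <- function(ring, tol) {
  if (tol <= 0 || nrow(ring) <= 4L) return(ring)
  n <- nrow(ring)
  d0 <- (ring[, 1L] - ring[1L, 1L])^2 + (ring[, 2L] - ring[1L, 2L])^2
  k <- which.max(d0)
  if (k == 1L) return(ring)
  half1 <- dp_open(ring[1:k, , drop = FALSE], tol)
  half2 <- dp_open(ring[c(k:n, 1L), , drop = FALSE], tol)
  out <- rbind(half1, half2[-c(1L, nrow(half2)), , drop = FALSE])
  if (nrow(out) < 3L) ring else out
}

dp_open <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  keep <- logical(n); keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    if (j - i < 2L) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    mid <- (i + 1L):(j - 1L)
    if (len2 == 0) {
      d <- sqrt((pts[mid, 1L] - a[1L])^2 + (pts[mid, 2L] - a[2L])^2)
    } else {
      t <- ((pts[mid, 1L] - a[1L]) * ab[1L] +
              (pts[mid, 2L] - a[2L]) * ab[2L]) / len2
      t <- pmin(pmax(t, 0), 1)
      d <- sqrt((pts[mid, 1L] - (a[1L] + t * ab[1L]))^2 +
                  (pts[mid, 2L] - (a[2L] + t * ab[2L]))^2)
    }
    kmax <- which.max(d)
    if (d[kmax] > tol) {
      k <- mid[kmax]
      keep[k] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  pts[keep, , drop = FALSE]
}

# Signed shoelace area of a ring (n x 2, not closed).
ring_signed_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Extract crown polygons from a cleaned mask
#'
#' One polygon per 8-connected vegetation component. Boundaries are traced on
#' pixel edges (so the raw polygon area equals pixel count times pixel area
#' exactly), then Douglas-Peucker simplified with tolerance `simplify_tol_m`
#' (default twice the GSD). Interior holes are kept as additional rings.
#' Component ids are sequential in (top-most, then left-most) pixel order.
#'
#' @param mask a cleaned `forest_mask`.
#' @param simplify_tol_m simplification tolerance (m); 0 keeps the pixel
#'   staircase exactly.
#' @return a `crown_set`: tibble with `id`, `class_label` (NA until
#'   [classify_crowns()]), `n_pixels`, `area_m2` and a `geometry`
#'   list-column (each element a list of rings; first ring is the exterior,
#'   rows are `(x, y)` vertices, not closed).
#' @export
extract_crown_polygons <- function(mask, simplify_tol_m = NULL) {
  stopifnot(inherits(mask, "forest_mask"))
  g <- mask$grid
  if (is.null(simplify_tol_m)) simplify_tol_m <- 2 * g$px
  lab <- label_components(g$values)
  nlab <- max(lab)
  if (nlab == 0L) {
    return(new_crown_set(tibble::tibble(
      id = integer(0), class_label = integer(0), n_pixels = integer(0),
      area_m2 = numeric(0), geometry = list()), g))
  }
  rows_of <- (which(lab > 0L) - 1L) %% nrow(lab) + 1L
  cols_of <- (which(lab > 0L) - 1L) %/% nrow(lab) + 1L
  labs <- lab[lab > 0L]
  out <- vector("list", nlab)
  for (comp in seq_len(nlab)) {
    sel <- labs == comp
    r <- rows_of[sel]; c_ <- cols_of[sel]
    r0 <- min(r); c0 <- min(c_)
    m <- matrix(FALSE, max(r) - r0 + 1L, max(c_) - c0 + 1L)
    m[cbind(r - r0 + 1L, c_ - c0 + 1L)] <- TRUE
    rings_px <- trace_rings_px(m)
    rings <- lapply(rings_px, function(rp) {
      # lattice corner (c, r) within bbox -> map coordinates
      cc <- rp[, 1L] + (c0 - 1L)
      rr <- rp[, 2L] + (r0 - 1L)
      ring <- cbind(x = g$xmin + cc * g$px, y = g$ymax - rr * g$py)
      ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]  # exterior CCW
      simplify_ring(drop_collinear(ring), simplify_tol_m)
    })
    areas <- vapply(rings, ring_signed_area, numeric(1L))
    ord <- order(-abs(areas))
    rings <- rings[ord]; areas <- areas[ord]
    out[[comp]] <- list(rings = rings, area = sum(areas),
                        n_pixels = sum(sel))
  }
  new_crown_set(tibble::tibble(
    id = seq_len(nlab),
    class_label = NA_integer_,
    n_pixels = vapply(out, `[[`, integer(1L), "n_pixels"),
    area_m2 = vapply(out, `[[`, numeric(1L), "area"),
    geometry = lapply(out, `[[`, "rings")), g)
}

new_crown_set <- function(df, grid) {
  structure(df, class = c("crown_set", class(tibble::tibble()))) |>
    (\(x) { attr(x, "crs") <- grid$crs; attr(x, "gsd") <- grid$px; x })()
}

#' Pixel membership of crown polygons
#'
#' A pixel belongs to a crown iff its centre is inside the polygon (even-odd
#' rule over all rings, boundary counts as inside) — the single zonal
#' convention used throughout the package.
#'
#' @param grid reference `forest_grid`.
#' @param rings list of ring matrices (first exterior).
#' @return two-column matrix `(row, col)` of member pixel indices.
#' @keywords internal
polygon_pixel_members <- function(grid, rings) {
  ax <- grid_axes(grid)
  outer_ring <- rings[[1L]]
  rows <- which(ax$y <= max(outer_ring[, 2L]) & ax$y >= min(outer_ring[, 2L]))
  cols <- which(ax$x >= min(outer_ring[, 1L]) & ax$x <= max(outer_ring[, 1L]))
  if (length(rows) == 0L || length(cols) == 0L) {
    return(cbind(row = integer(0), col = integer(0)))
  }
  px <- rep(ax$x[cols], each = length(rows))
  py <- rep(ax$y[rows], times = length(cols))
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (ring in rings) {
    res <- sp::point.in.polygon(px, py, ring[, 1L], ring[, 2L])
    inside <- xor(inside, res == 1L)
    on_edge <- on_edge | res >= 2L
  }
  keep <- inside | on_edge
  cbind(row = rep(rows, times = length(cols))[keep],
        col = rep(cols, each = length(rows))[keep])
}

#' Split crowns into classes by mean index
#'
#' Computes each crown's mean index over its interior pixels and cuts the
#' distribution of means at equal-count quantile breaks into `k` classes
#' (class 1 = lowest index). Ties at a break go to the lower class;
#' identical means put every crown in class 1. Deterministic.
#'
#' @param index a `forest_index` (same grid as the crowns' source mask).
#' @param crowns a `crown_set`.
#' @param k number of classes (default 3).
#' @return `crowns` with `class_label` filled and a `mean_index` column.
#' @export
classify_crowns <- function(index, crowns, k = 3L) {
  stopifnot(inherits(index, "forest_index"), inherits(crowns, "crown_set"))
  if (nrow(crowns) < k) {
    stop("need at least k = ", k, " crowns, got ", nrow(crowns), call. = FALSE)
  }
  g <- index$grid
  means <- vapply(crowns$geometry, function(rings) {
    mem <- polygon_pixel_members(g, rings)
    vals <- g$values[mem]
    mean(vals, na.rm = TRUE)
  }, numeric(1L))
  if (k == 1L) {
    label <- rep(1L, length(means))
  } else {
    breaks <- stats::quantile(means, probs = seq_len(k - 1L) / k,
                              type = 7, names = FALSE)
    label <- 1L + vapply(means, function(m) sum(m > breaks), integer(1L))
  }
  crowns$class_label <- label
  crowns$mean_index <- means
  crowns
}

#' Between-class separability of each colour index
#'
#' Programmatic stand-in for choosing the masking index by visual
#' inspection: for each of the 12 indices, the Fisher separability
#' `(mu_veg - mu_ground)^2 / (sd_veg^2 + sd_ground^2)` between pixels under
#' a vegetation reference and the rest.
#'
#' @param bands a `forest_bands`.
#' @param reference a `forest_grid` (or `forest_mask`) where values > 0 mark
#'   vegetation.
#' @return a tibble (`index`, `mean_veg`, `mean_ground`, `fisher`) sorted by
#'   decreasing separability.
#' @export
index_separability <- function(bands, reference) {
  ref <- if (inherits(reference, "forest_mask")) reference$grid else reference
  veg <- !is.na(ref$values) & ref$values > 0
  gnd <- !is.na(ref$values) & ref$values == 0
  rows <- purrr::map(colour_index_names(), function(nm) {
    v <- compute_index(bands, nm)$grid$values
    m1 <- mean(v[veg], na.rm = TRUE); m0 <- mean(v[gnd], na.rm = TRUE)
    s1 <- stats::sd(v[veg], na.rm = TRUE); s0 <- stats::sd(v[gnd], na.rm = TRUE)
    tibble::tibble(index = nm, mean_veg = m1, mean_ground = m0,
                   fisher = (m1 - m0)^2 / (s1^2 + s0^2))
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$fisher))
}

# ---- GeoJSON ----------------------------------------------------------------

#' Write / read crown polygons as GeoJSON
#'
#' Standard RFC 7946 FeatureCollection with `id`, `class_label`, `area_m2`
#' (and `mean_index` when present) as feature properties.
#'
#' @param crowns a `crown_set`.
#' @param path output / input file path.
#' @return `path` invisibly; `read_crowns_geojson()` returns a `crown_set`.
#' @export
write_crowns_geojson <- function(crowns, path) {
  features <- purrr::map(seq_len(nrow(crowns)), function(i) {
    rings <- crowns$geometry[[i]]
    coords <- lapply(rings, function(rg) {
      closed <- rbind(rg, rg[1L, , drop = FALSE])
      lapply(seq_len(nrow(closed)), function(j) c(closed[j, 1L], closed[j, 2L]))
    })
    props <- list(id = crowns$id[i], class_label = crowns$class_label[i],
                  area_m2 = crowns$area_m2[i], n_pixels = crowns$n_pixels[i])
    if ("mean_index" %in% names(crowns)) props$mean_index <- crowns$mean_index[i]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  doc <- list(type = "FeatureCollection",
              crs_tag = if (is.null(attr(crowns, "crs"))) NA else attr(crowns, "crs"),
              features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_crowns_geojson
#' @export
read_crowns_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  rows <- purrr::map(doc$features, function(f) {
    rings <- lapply(f$geometry$coordinates, function(cr) {
      m <- do.call(rbind, lapply(cr, function(p) c(p[[1L]], p[[2L]])))
      colnames(m) <- c("x", "y")
      m[-nrow(m), , drop = FALSE]          # drop closing vertex
    })
    p <- f$properties
    tibble::tibble(id = as.integer(p$id),
                   class_label = if (is.null(p$class_label)) NA_integer_
                                 else as.integer(p$class_label),
                   n_pixels = as.integer(p$n_pixels %||% NA_integer_),
                   area_m2 = as.numeric(p$area_m2),
                   mean_index = as.numeric(p$mean_index %||% NA_real_),
                   geometry = list(rings))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("crown_set", class(tibble::tibble())),
            crs = doc$crs_tag)
}

#' @importFrom rlang %||% .data
NULL
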