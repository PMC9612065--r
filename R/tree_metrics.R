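# Per-crown zonal statistics on the CHM — the forest-inventory product.

#' Zonal height statistics per crown
#'
#' For each crown polygon, statistics of the CHM over the pixels whose
#' centres fall inside the polygon (even-odd rule over exterior and hole
#' rings; boundary counts as inside). Crowns without any valid member pixel
#' are flagged `empty = TRUE` with NA statistics. The 95th percentile uses
#' linear interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param chm a `forest_grid`.
#' @param crowns a `crown_set`.
#' @return a tibble (`crown_id, class_label, n_pixels, height_max,
#'   height_mean, height_sd, height_p95, crown_area_m2, empty`).
#' @export
zonal_stats <- function(chm, crowns) {
  stopifnot(is_grid(chm), inherits(crowns, "crown_set"))
  crs_c <- attr(crowns, "crs")
  if (!is.null(crs_c) && !is.na(crs_c) && !is.na(chm$crs) &&
      !identical(crs_c, chm$crs)) {
    stop("crowns and CHM are in different CRSs (", crs_c, " vs ", chm$crs,
         ")", call. = FALSE)
  }
  rows <- purrr::map(seq_len(nrow(crowns)), function(i) {
    mem <- polygon_pixel_members(chm, crowns$geometry[[i]])
    vals <- chm$values[mem]
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    if (n == 0L) {
      tibble::tibble(crown_id = crowns$id[i],
                     class_label = crowns$class_label[i],
                     n_pixels = 0L, height_max = NA_real_,
                     height_mean = NA_real_, height_sd = NA_real_,
                     height_p95 = NA_real_,
                     crown_area_m2 = crowns$area_m2[i], empty = TRUE)
    } else {
      tibble::tibble(crown_id = crowns$id[i],
                     class_label = crowns$class_label[i],
                     n_pixels = n,
                     height_max = max(vals),
                     height_mean = mean(vals),
                     height_sd = if (n > 1L) stats::sd(vals) else 0,
                     height_p95 = stats::quantile(vals, 0.95, type = 7,
                                                  names = FALSE),
                     crown_area_m2 = crowns$area_m2[i], empty = FALSE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Area of a crown polygon
#'
#' Shoelace area of the exterior ring minus the area of any holes.
#'
#' @param rings a list of ring matrices (`(x, y)` rows, exterior first,
#'   holes with opposite orientation), or a single ring matrix.
#' @return area in m^2.
#' @export
crown_area <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  areas <- vapply(rings, ring_signed_area, numeric(1L))
  if (any(abs(areas) == 0)) stop("degenerate ring with zero area", call. = FALSE)
  # exterior carries the sign; holes are opposite-signed, so the signed sum
  # is the net area
  a <- sum(areas)
  if (a <= 0 && areas[1L] < 0) a <- -a      # accept clockwise exteriors too
  a
}

#' Per-class inventory summary
#'
#' Aggregates zonal statistics per crown class: crown count, mean height
#' (of per-crown maxima), and total crown area, plus a grand-total row.
#' Empty crowns are excluded. Deterministic ordering by class.
#'
#' @param stats output of [zonal_stats()].
#' @return a tibble (`class_label, n_crowns, mean_height_m, total_crown_area_m2`),
#'   last row `class_label = NA` holding the totals.
#' @export
inventory_table <- function(stats) {
  if (nrow(stats) == 0L) stop("empty statistics table", call. = FALSE)
  used <- dplyr::filter(stats, !.data$empty)
  per_class <- used |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(n_crowns = dplyr::n(),
                     mean_height_m = mean(.data$height_max),
                     total_crown_area_m2 = sum(.data$crown_area_m2),
                     .groups = "drop") |>
    dplyr::arrange(.data$class_label)
  total <- tibble::tibble(class_label = NA_integer_,
                          n_crowns = nrow(used),
                          mean_height_m = mean(used$height_max),
                          total_crown_area_m2 = sum(used$crown_area_m2))
  dplyr::bind_rows(per_class, total)
}

#' Write tree statistics / inventory to CSV
#'
#' @param stats a tibble from [zonal_stats()] or [inventory_table()].
#' @param path output CSV path.
#' @export
write_stats_csv <- function(stats, path) {
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
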