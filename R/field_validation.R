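# Validation of CHM heights against field-measured tree heights.
#
# Field stems are matched to the CHM purely spatially: the maximum CHM value
# within a 1 m buffer of each recorded stem position (the buffer absorbs
# GNSS error of up to ~0.10 m). The paired heights then go through a
# Pearson correlation test (two-sided, Student t with n - 2 df) plus OLS fit
# and agreement diagnostics.

#' Maximum CHM height within a buffer of each field point
#'
#' For each field point, the maximum over valid CHM pixels whose centres lie
#' within Euclidean distance `radius_m` of the point. Points with no valid
#' pixel in the buffer are excluded from the pair table and counted in
#' `attr(, "n_excluded")`.
#'
#' @param chm a `forest_grid`.
#' @param points tibble of field points (`id, x, y, height_m`, ...).
#' @param radius_m buffer radius in metres (default 1.0).
#' @return a tibble (`point_id, field_height, chm_height, n_buffer_pixels`)
#'   with the exclusion count as an attribute.
#' @export
buffer_max_height <- function(chm, points, radius_m = 1.0) {
  stopifnot(is_grid(chm), radius_m > 0)
  ax <- grid_axes(chm)
  rows <- purrr::map(seq_len(nrow(points)), function(i) {
    px <- points$x[i]; py <- points$y[i]
    cs <- which(abs(ax$x - px) <= radius_m)
    rs <- which(abs(ax$y - py) <= radius_m)
    if (length(cs) == 0L || length(rs) == 0L) {
      return(tibble::tibble(point_id = points$id[i],
                            field_height = points$height_m[i],
                            chm_height = NA_real_, n_buffer_pixels = 0L))
    }
    d2 <- outer((ax$y[rs] - py)^2, (ax$x[cs] - px)^2, `+`)
    vals <- chm$values[rs, cs, drop = FALSE]
    sel <- d2 <= radius_m^2 & !is.na(vals)
    tibble::tibble(point_id = points$id[i],
                   field_height = points$height_m[i],
                   chm_height = if (any(sel)) max(vals[sel]) else NA_real_,
                   n_buffer_pixels = sum(sel))
  })
  out <- dplyr::bind_rows(rows)
  excluded <- is.na(out$chm_height)
  res <- out[!excluded, ]
  attr(res, "n_excluded") <- sum(excluded)
  attr(res, "excluded_ids") <- out$point_id[excluded]
  res
}

#' Pearson correlation test on paired heights
#'
#' Hand-computed Pearson r, its two-sided p-value from the Student t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom (`p = 0` at `|r| = 1`), the OLS fit of field height on CHM height,
#' the residual RMSE of that fit, and the mean bias `mean(chm - field)`.
#'
#' @param pairs tibble from [buffer_max_height()] (columns `field_height`,
#'   `chm_height`).
#' @return an object of class `chm_validation`.
#' @export
pearson_test <- function(pairs) {
  x <- pairs$chm_height; y <- pairs$field_height
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs for a correlation test", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("a constant variable has no defined correlation", call. = FALSE)
  }
  dx <- x - mean(x); dy <- y - mean(y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  slope <- sum(dx * dy) / sum(dx^2)           # field regressed on chm
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  structure(list(n = n, pearson_r = r, p_value = p,
                 slope = slope, intercept = intercept,
                 rmse = sqrt(mean(resid^2)),
                 bias = mean(x - y),
                 n_excluded = attr(pairs, "n_excluded") %||% 0L,
                 pairs = tibble::as_tibble(pairs)),
            class = "chm_validation")
}

#' @export
print.chm_validation <- function(x, ...) {
  cat(sprintf("<chm_validation> n = %d pairs (%d excluded)\n", x$n,
              x$n_excluded))
  cat(sprintf("  Pearson r = %.4f, two-sided p = %.3g\n", x$pearson_r,
              x$p_value))
  cat(sprintf("  field ~ chm: slope = %.3f, intercept = %.3f, rmse = %.3f m\n",
              x$slope, x$intercept, x$rmse))
  cat(sprintf("  bias (chm - field) = %.3f m\n", x$bias))
  invisible(x)
}

#' Tidy the validation fit
#'
#' `tidy()` returns the OLS terms of the field-on-CHM fit; `glance()` the
#' one-row model summary (n, r, p, rmse, bias, exclusions).
#'
#' @param x a `chm_validation`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.chm_validation <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "chm_height"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.chm_validation
#' @exportS3Method generics::glance
glance.chm_validation <- function(x, ...) {
  tibble::tibble(n = x$n, pearson_r = x$pearson_r, p_value = x$p_value,
                 slope = x$slope, intercept = x$intercept,
                 rmse = x$rmse, bias = x$bias, n_excluded = x$n_excluded)
}

#' Scatter plot of field versus CHM heights
#'
#' Per-pair scatter with the OLS fit, the 1:1 line and the correlation
#' annotation.
#'
#' @param object a `chm_validation`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.chm_validation <- function(object, ...) {
  lab <- sprintf("r = %.3f, p %s", object$pearson_r,
                 if (object$p_value < 1e-4) "< 0.0001"
                 else sprintf("= %.3g", object$p_value))
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$chm_height, y = .data$field_height)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2166ac") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = lab) +
    ggplot2::labs(x = "CHM height (m, 1 m buffer max)",
                  y = "Field-measured height (m)")
}

#' Machine-readable validation report
#'
#' Writes (or returns) the summary statistics plus the per-pair table used
#' to compute them; recomputing r from the emitted pairs reproduces the
#' reported r exactly.
#'
#' @param result a `chm_validation`.
#' @param path optional JSON output path.
#' @return list with `summary` (named list) and `pairs` (tibble), invisibly
#'   if written.
#' @export
validation_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "chm_validation"))
  report <- list(
    summary = list(n = result$n, pearson_r = result$pearson_r,
                   p_value = result$p_value, slope = result$slope,
                   intercept = result$intercept, rmse = result$rmse,
                   bias = result$bias, n_excluded = result$n_excluded),
    pairs = result$pairs
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Read / write field survey points as CSV
#'
#' Column layout `id, x, y, height_m, dbh_cm`. Reading enforces the survey
#' inclusion rule (`dbh_cm >= 10`) and positive heights.
#'
#' @param points tibble of field points.
#' @param path CSV path.
#' @export
write_field_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "x", "y", "height_m")
  if (!all(need %in% names(df))) {
    stop("field CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$height_m <= 0)) stop("field heights must be positive", call. = FALSE)
  if (!is.null(df$dbh_cm) && any(df$dbh_cm < 10)) {
    stop("field records below the 10 cm DBH inclusion rule", call. = FALSE)
  }
  tibble::as_tibble(df)
}
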