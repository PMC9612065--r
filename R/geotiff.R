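# Minimal GeoTIFF codec.
#
# Scope: uncompressed, strip-based, chunky (pixel-interleaved) baseline TIFF
# with the GeoTIFF georeferencing tags (ModelPixelScale, ModelTiepoint,
# GeoKeyDirectory) and the GDAL nodata tag. Sample types: uint8, uint16,
# float32. Reads either byte order; writes little-endian. Tiled or compressed
# files are rejected with a clear error. This covers every raster the
# pipeline produces and the plain GeoTIFFs that mapping tools export.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

#' Round to float32 precision
#'
#' Values written to a float32 GeoTIFF come back at float32 precision; this
#' applies the same rounding in memory, so round-trip tests can be exact.
#'
#' @param x numeric vector or matrix.
#' @return `x` rounded to the nearest representable float32.
#' @export
as_float32 <- function(x) {
  v <- readBin(writeBin(as.vector(as.numeric(x)), raw(), size = 4L),
               "double", size = 4L, n = length(x))
  if (is.matrix(x)) v <- matrix(v, nrow(x), ncol(x))
  v
}

# ---- writer -----------------------------------------------------------------

tiff_entry <- function(tag, type, values, external) {
  size <- TIFF_TYPE_SIZES[[as.character(type)]]
  if (type == 2L) {                      # ASCII: append NUL
    raw_val <- c(charToRaw(values), as.raw(0L))
    count <- length(raw_val)
  } else {
    count <- length(values)
    raw_val <- switch(as.character(type),
      `3` = writeBin(as.integer(values), raw(), size = 2L, endian = "little"),
      `4` = writeBin(as.integer(values), raw(), size = 4L, endian = "little"),
      `12` = writeBin(as.numeric(values), raw(), size = 8L, endian = "little"),
      stop("unsupported tag type for writing: ", type))
  }
  list(tag = tag, type = type, count = count, raw = raw_val,
       inline = length(raw_val) <= 4L)
}

encode_payload <- function(bands, dtype, nodata) {
  nb <- length(bands); nr <- nrow(bands[[1L]]); nc <- ncol(bands[[1L]])
  arr <- array(0, dim = c(nb, nc, nr))
  for (b in seq_len(nb)) {
    v <- bands[[b]]
    if (dtype == "float32") {
      v[is.na(v)] <- nodata
    } else if (anyNA(v)) {
      stop("NA pixels cannot be written with an integer sample type",
           call. = FALSE)
    }
    arr[b, , ] <- t(v)
  }
  v <- as.vector(arr)
  switch(dtype,
    float32 = writeBin(as.numeric(v), raw(), size = 4L, endian = "little"),
    uint8   = as.raw(as.integer(v)),
    uint16  = writeBin(as.integer(v), raw(), size = 2L, endian = "little"))
}

crs_epsg <- function(crs) {
  if (is.na(crs)) return(NA_integer_)
  m <- regmatches(crs, regexpr("[0-9]+$", crs))
  if (length(m) == 0L) NA_integer_ else as.integer(m)
}

epsg_is_geographic <- function(code) !is.na(code) && code >= 4001L && code <= 4999L

#' Write a raster to GeoTIFF
#'
#' Single grids are written as one band, `forest_rgb` objects as three bands
#' (pixel-interleaved). `NA` pixels are stored as the grid's nodata sentinel
#' (float32 only). The georeference is stored in standard GeoTIFF tags so the
#' files open in QGIS/GDAL-based tools.
#'
#' @param x a `forest_grid` or `forest_rgb`.
#' @param path output file path.
#' @param dtype `"float32"` (default for grids), `"uint8"` or `"uint16"`
#'   (default for RGB when the values fit).
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, dtype = NULL) {
  if (is_grid(x)) {
    bands <- list(x$values); ref <- x
    if (is.null(dtype)) dtype <- "float32"
  } else if (is_rgb(x)) {
    stop_if_misaligned(x$red, x$green, x$blue, what = "RGB bands")
    bands <- list(x$red$values, x$green$values, x$blue$values); ref <- x$red
    if (is.null(dtype)) {
      v <- unlist(lapply(bands, range), use.names = FALSE)
      dtype <- if (all(bands[[1L]] == round(bands[[1L]]), na.rm = TRUE) &&
                   max(v) <= 255 && min(v) >= 0) "uint8" else "float32"
    }
  } else if (is.list(x) && all(vapply(x, is_grid, logical(1L)))) {
    do.call(stop_if_misaligned, c(x, list(what = "bands")))
    bands <- lapply(x, `[[`, "values"); ref <- x[[1L]]
    if (is.null(dtype)) dtype <- "float32"
  } else {
    stop("write_raster() expects a forest_grid, forest_rgb or list of grids",
         call. = FALSE)
  }
  dtype <- match.arg(dtype, c("float32", "uint8", "uint16"))
  nb <- length(bands); nr <- nrow(bands[[1L]]); nc <- ncol(bands[[1L]])
  payload <- encode_payload(bands, dtype, ref$nodata)

  bits <- switch(dtype, float32 = 32L, uint8 = 8L, uint16 = 16L)
  fmt <- switch(dtype, float32 = 3L, uint8 = 1L, uint16 = 1L)
  data_offset <- 8L
  entries <- list(
    tiff_entry(256L, 4L, nc),                  # ImageWidth
    tiff_entry(257L, 4L, nr),                  # ImageLength
    tiff_entry(258L, 3L, rep(bits, nb)),       # BitsPerSample
    tiff_entry(259L, 3L, 1L),                  # Compression = none
    tiff_entry(262L, 3L, if (nb == 3L) 2L else 1L),  # Photometric
    tiff_entry(273L, 4L, data_offset),         # StripOffsets (single strip)
    tiff_entry(277L, 3L, nb),                  # SamplesPerPixel
    tiff_entry(278L, 4L, nr),                  # RowsPerStrip
    tiff_entry(279L, 4L, length(payload)),     # StripByteCounts
    tiff_entry(284L, 3L, 1L),                  # PlanarConfiguration = chunky
    tiff_entry(339L, 3L, rep(fmt, nb)),        # SampleFormat
    tiff_entry(33550L, 12L, c(ref$px, ref$py, 0)),            # ModelPixelScale
    tiff_entry(33922L, 12L, c(0, 0, 0, ref$xmin, ref$ymax, 0))# ModelTiepoint
  )
  code <- crs_epsg(ref$crs)
  if (!is.na(code)) {
    geo <- if (epsg_is_geographic(code)) {
      c(1L, 1L, 0L, 3L, 1024L, 0L, 1L, 2L, 1025L, 0L, 1L, 1L,
        2048L, 0L, 1L, code)
    } else {
      c(1L, 1L, 0L, 3L, 1024L, 0L, 1L, 1L, 1025L, 0L, 1L, 1L,
        3072L, 0L, 1L, code)
    }
    entries <- c(entries, list(tiff_entry(34735L, 3L, geo)))
  }
  entries <- c(entries, list(tiff_entry(42113L, 2L, format(ref$nodata))))
  entries <- entries[order(vapply(entries, `[[`, integer(1L), "tag"))]

  ifd_offset <- data_offset + length(payload)
  ifd_len <- 2L + 12L * length(entries) + 4L
  ext_offset <- ifd_offset + ifd_len
  ext <- raw(0L)
  entry_raw <- lapply(entries, function(e) {
    val4 <- if (e$inline) {
      c(e$raw, raw(4L - length(e$raw)))
    } else {
      off <- ext_offset + length(ext)
      ext <<- c(ext, e$raw)
      writeBin(as.integer(off), raw(), size = 4L, endian = "little")
    }
    c(writeBin(as.integer(e$tag), raw(), size = 2L, endian = "little"),
      writeBin(as.integer(e$type), raw(), size = 2L, endian = "little"),
      writeBin(as.integer(e$count), raw(), size = 4L, endian = "little"),
      val4)
  })

  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42L), con, size = 2L, endian = "little")
  writeBin(as.integer(data_offset + length(payload)), con, size = 4L,
           endian = "little")
  writeBin(payload, con)
  writeBin(as.integer(length(entries)), con, size = 2L, endian = "little")
  writeBin(do.call(c, entry_raw), con)
  writeBin(as.integer(0L), con, size = 4L, endian = "little")  # next IFD
  writeBin(ext, con)
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

read_tag_values <- function(raw_all, entry_raw, endian) {
  tag <- readBin(entry_raw[1:2], "integer", size = 2L, signed = FALSE,
                 endian = endian)
  type <- readBin(entry_raw[3:4], "integer", size = 2L, signed = FALSE,
                  endian = endian)
  count <- readBin(entry_raw[5:8], "integer", size = 4L, endian = endian)
  size <- TIFF_TYPE_SIZES[as.character(type)]
  if (is.na(size)) return(list(tag = tag, values = NULL))
  nbytes <- size * count
  raw_val <- if (nbytes <= 4L) {
    entry_raw[9:(8L + nbytes)]
  } else {
    off <- readBin(entry_raw[9:12], "integer", size = 4L, endian = endian)
    raw_all[(off + 1L):(off + nbytes)]
  }
  values <- switch(as.character(type),
    `1` = as.integer(raw_val),
    `2` = rawToChar(raw_val[raw_val != as.raw(0L)]),
    `3` = readBin(raw_val, "integer", size = 2L, signed = FALSE, n = count,
                  endian = endian),
    `4` = readBin(raw_val, "integer", size = 4L, n = count, endian = endian),
    `11` = readBin(raw_val, "double", size = 4L, n = count, endian = endian),
    `12` = readBin(raw_val, "double", size = 8L, n = count, endian = endian),
    NULL)
  list(tag = tag, values = values)
}

#' Read a GeoTIFF raster
#'
#' Reads an uncompressed, strip-based GeoTIFF. One-band files return a
#' `forest_grid`; three-band files a `forest_rgb`; anything else a list of
#' grids. A missing or geographic (degree-unit) CRS triggers a warning and the
#' result carries `attr(, "unit_ambiguous") = TRUE` — every downstream stage
#' assumes metre units.
#'
#' @param path GeoTIFF file path.
#' @param bands optional vector of 1-based band indices to keep.
#' @return a `forest_grid`, `forest_rgb`, or list of `forest_grid`s.
#' @export
read_raster <- function(path, bands = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path, call. = FALSE))
  ifd_off <- readBin(raw_all[5:8], "integer", size = 4L, endian = endian)
  n_entries <- readBin(raw_all[(ifd_off + 1L):(ifd_off + 2L)], "integer",
                       size = 2L, signed = FALSE, endian = endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    s <- ifd_off + 2L + (i - 1L) * 12L
    e <- read_tag_values(raw_all, raw_all[(s + 1L):(s + 12L)], endian)
    tags[[as.character(e$tag)]] <- e$values
  }
  tg <- function(code, default = NULL) {
    v <- tags[[as.character(code)]]
    if (is.null(v)) default else v
  }
  if (!is.null(tg(322L)) || !is.null(tg(324L))) {
    stop("tiled TIFFs are not supported; rewrite as strip-based", call. = FALSE)
  }
  if (tg(259L, 1L)[1L] != 1L) {
    stop("compressed TIFFs are not supported", call. = FALSE)
  }
  if (tg(284L, 1L)[1L] != 1L) {
    stop("planar (band-sequential) TIFFs are not supported", call. = FALSE)
  }
  nc <- tg(256L); nr <- tg(257L)
  nb <- tg(277L, 1L)[1L]
  bits <- tg(258L, 8L)[1L]
  fmt <- tg(339L, 1L)[1L]

  offs <- tg(273L); cnts <- tg(279L)
  payload <- do.call(c, lapply(seq_along(offs), function(i) {
    raw_all[(offs[i] + 1L):(offs[i] + cnts[i])]
  }))
  n_vals <- nr * nc * nb
  vals <- if (fmt == 3L && bits == 32L) {
    readBin(payload, "double", size = 4L, n = n_vals, endian = endian)
  } else if (fmt %in% c(1L, 2L) && bits == 8L) {
    as.numeric(as.integer(payload[seq_len(n_vals)]))
  } else if (fmt %in% c(1L, 2L) && bits == 16L) {
    as.numeric(readBin(payload, "integer", size = 2L, signed = (fmt == 2L),
                       n = n_vals, endian = endian))
  } else {
    stop("unsupported sample type: format ", fmt, ", ", bits, " bits",
         call. = FALSE)
  }
  arr <- array(vals, dim = c(nb, nc, nr))

  scale <- tg(33550L); tiepoint <- tg(33922L)
  if (is.null(scale) || is.null(tiepoint)) {
    warning("no GeoTIFF georeference tags; assuming 1 m pixels at origin (0, ",
            nr, ")", call. = FALSE)
    px <- 1; py <- 1; xmin <- 0; ymax <- nr
  } else {
    px <- scale[1L]; py <- scale[2L]
    xmin <- tiepoint[4L] - tiepoint[1L] * px
    ymax <- tiepoint[5L] + tiepoint[2L] * py
  }
  geo <- tg(34735L)
  unit_ambiguous <- FALSE
  crs <- NA_character_
  if (is.null(geo)) {
    warning("no CRS in file; downstream stages assume projected metre units",
            call. = FALSE)
    unit_ambiguous <- TRUE
  } else {
    keys <- matrix(geo[-(1:4)], ncol = 4L, byrow = TRUE)
    model <- keys[keys[, 1L] == 1024L, 4L]
    code <- c(keys[keys[, 1L] == 3072L, 4L], keys[keys[, 1L] == 2048L, 4L])
    if (length(code) > 0L) crs <- paste0("EPSG:", code[1L])
    if (length(model) > 0L && model[1L] == 2L) {
      warning("geographic (degree-unit) CRS ", crs,
              "; downstream stages assume metre units", call. = FALSE)
      unit_ambiguous <- TRUE
    }
  }
  nodata <- suppressWarnings(as.numeric(tg(42113L, NA_character_)))

  make_band <- function(b) {
    v <- t(arr[b, , , drop = TRUE])
    if (!is.matrix(v)) v <- matrix(v, nrow = nr, ncol = nc)
    if (!is.na(nodata)) v[v == nodata] <- NA_real_
    grid_create(v, xmin, ymax, c(px, py), crs = crs,
                nodata = if (is.na(nodata)) -9999 else nodata)
  }
  if (is.null(bands)) bands <- seq_len(nb)
  if (any(bands < 1L | bands > nb)) {
    stop("band index out of range: file has ", nb, " band(s)", call. = FALSE)
  }
  grids <- lapply(bands, make_band)
  out <- if (length(grids) == 1L) {
    grids[[1L]]
  } else if (length(grids) == 3L) {
    rgb_orthomosaic(grids[[1L]], grids[[2L]], grids[[3L]])
  } else {
    grids
  }
  attr(out, "unit_ambiguous") <- unit_ambiguous
  out
}
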