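# RGB band normalisation and the twelve colour indices.
#
# All indices are evaluated on the NORMALISED band fractions
#   r = R/(R+G+B), g = G/(R+G+B), b = B/(R+G+B),
# so they are invariant to any positive rescaling of the raw digital numbers
# (illumination / exposure). Denominators within 1e-12 of zero yield nodata
# rather than infinities, so downstream thresholding never sees them.

DEN_EPS <- 1e-12

#' Names of the supported colour indices
#'
#' The closed set of RGB colour indices, in canonical order: VARI, ExG, ExR,
#' ExB, ExGR, NGRDI, NGBDI, MGRVI, WI, IKAW, GLA, RGBVI. NGBDI — the
#' green-blue normalised difference `(g - b) / (g + b)` — is the default
#' index for separating tree crowns from ground.
#'
#' @return character vector of the 12 index names.
#' @export
colour_index_names <- function() {
  c("VARI", "ExG", "ExR", "ExB", "ExGR", "NGRDI", "NGBDI", "MGRVI",
    "WI", "IKAW", "GLA", "RGBVI")
}

#' Normalise orthomosaic bands to fractions
#'
#' `r = R/(R+G+B)`, `g = G/(R+G+B)`, `b = B/(R+G+B)` per pixel. Pixels where
#' the band sum is zero, or where any band is nodata, are nodata in all three
#' outputs. At every valid pixel `r + g + b = 1`.
#'
#' @param image a `forest_rgb`.
#' @return an object of class `forest_bands`: list of three aligned grids
#'   `r`, `g`, `b`.
#' @export
normalize_bands <- function(image) {
  stopifnot(is_rgb(image))
  R <- image$red$values; G <- image$green$values; B <- image$blue$values
  s <- R + G + B
  s[!is.na(s) & s == 0] <- NA_real_
  structure(list(r = grid_like(image$red, R / s),
                 g = grid_like(image$green, G / s),
                 b = grid_like(image$blue, B / s)),
            class = "forest_bands")
}

#' @export
print.forest_bands <- function(x, ...) {
  cat("<forest_bands> normalised r, g, b fractions\n")
  print(x$r)
  invisible(x)
}

# Index formulas on normalised fractions. `safe_div` guards denominators.
safe_div <- function(num, den) {
  den[!is.na(den) & abs(den) < DEN_EPS] <- NA_real_
  num / den
}

index_formula <- function(name, r, g, b) {
  switch(name,
    VARI  = safe_div(g - r, g + r - b),
    ExG   = 2 * g - r - b,
    ExR   = 1.4 * r - g,
    ExB   = 1.4 * b - g,
    ExGR  = (2 * g - r - b) - (1.4 * r - g),
    NGRDI = safe_div(g - r, g + r),
    NGBDI = safe_div(g - b, g + b),
    MGRVI = safe_div(g^2 - r^2, g^2 + r^2),
    WI    = safe_div(g - b, r - g),
    IKAW  = safe_div(r - b, r + b),
    GLA   = safe_div(2 * g - r - b, 2 * g + r + b),
    RGBVI = safe_div(g^2 - b * r, g^2 + b * r),
    stop("unknown colour index: ", name, call. = FALSE))
}

#' Compute one colour index
#'
#' Pixelwise evaluation of the named index on normalised bands. Input nodata
#' propagates; a vanishing denominator (VARI at `g + r = b`, WI at `r = g`)
#' yields nodata.
#'
#' @param bands a `forest_bands` from [normalize_bands()].
#' @param name one of [colour_index_names()].
#' @return an object of class `forest_index`: list with `name` and `grid`.
#' @examples
#' # at (r, g, b) = (0.30, 0.50, 0.20): NGBDI = 0.3/0.7, VARI = 0.2/0.6
#' @export
compute_index <- function(bands, name) {
  stopifnot(inherits(bands, "forest_bands"))
  name <- match.arg(name, colour_index_names())
  v <- index_formula(name, bands$r$values, bands$g$values, bands$b$values)
  structure(list(name = name, grid = grid_like(bands$r, v)),
            class = "forest_index")
}

#' @export
print.forest_index <- function(x, ...) {
  cat("<forest_index>", x$name, "\n")
  print(x$grid)
  invisible(x)
}

#' Compute all twelve colour indices
#'
#' @param bands a `forest_bands`.
#' @return named list of 12 `forest_index` objects in canonical order.
#' @export
compute_all_indices <- function(bands) {
  out <- lapply(colour_index_names(), function(nm) compute_index(bands, nm))
  names(out) <- colour_index_names()
  out
}

#' Colour indices of single pixels
#'
#' Scalar/tabular convenience for worked examples and tests: takes raw band
#' values, normalises, and returns all 12 indices per pixel.
#'
#' @param R,G,B numeric vectors of raw band values (recycled to a common
#'   length).
#' @return a tibble with columns `r`, `g`, `b` and one column per index.
#' @export
pixel_indices <- function(R, G, B) {
  n <- max(length(R), length(G), length(B))
  R <- rep_len(as.numeric(R), n); G <- rep_len(as.numeric(G), n)
  B <- rep_len(as.numeric(B), n)
  s <- R + G + B
  s[s == 0] <- NA_real_
  r <- R / s; g <- G / s; b <- B / s
  out <- tibble::tibble(r = r, g = g, b = b)
  for (nm in colour_index_names()) out[[nm]] <- index_formula(nm, r, g, b)
  out
}
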