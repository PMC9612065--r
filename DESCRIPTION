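Package: forestchm
Title: Drone RGB Forest Inventory via Colour Indices and Canopy Height Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for individual-tree forest inventory from
    consumer-drone photogrammetry products. Computes normalised RGB colour
    indices from an orthomosaic, separates tree crowns from ground by index
    thresholding, derives a digital elevation model from randomly sampled
    ground points and a canopy height model (CHM = DSM - DEM), extracts
    per-crown height and area statistics by zonal operations, and validates
    CHM heights against field-measured tree heights with a buffered-maximum
    match and a Pearson correlation test. Includes a seedable synthetic
    forest-scene generator (terrain, paraboloid crowns, RGB rendering with
    shadows and sensor noise, simulated GNSS field survey) that reproduces
    the statistical structure of a private-native-forest validation study,
    plus minimal GeoTIFF and GeoJSON input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    stats,
    generics,
    ggplot2,
    jsonlite,
    interp,
    sp,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    deldir,
    optparse,
    withr
Config/testthat/edition: 3
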