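# forestchm

Individual-tree forest inventory from consumer-drone RGB photogrammetry.

Private native eucalypt forests are rarely inventoried: field plots are
laborious and airborne LiDAR is cost-prohibitive at the property scale. A
small drone with a plain RGB camera, flown over a stand and processed into an
orthomosaic and a digital surface model (DSM), carries enough information to
count tree crowns and estimate their heights. `forestchm` implements that
analysis end to end:

1. **Colour indices.** The orthomosaic bands are normalised to fractions
   `r = R/(R+G+B)`, `g = G/(R+G+B)`, `b = B/(R+G+B)` and twelve colour
   indices are computed from them (VARI, ExG, ExR, ExB, ExGR, NGRDI, NGBDI,
   MGRVI, WI, IKAW, GLA, RGBVI). Working on normalised fractions makes every
   index invariant to exposure and illumination scaling.
2. **Crown separation.** The green–blue normalised difference
   `NGBDI = (g − b)/(g + b)` separates tree crowns from ground, grass and
   shadow. The index raster is thresholded (Otsu's method by default),
   cleaned morphologically, and each 8-connected vegetation component is
   traced into one simplified crown polygon with an id, an area, and a
   class label from quantile breaks of the per-crown mean index.
3. **Canopy height model.** Random points are sampled on the non-vegetation
   (ground) pixels, their DSM elevations are interpolated into a digital
   elevation model (DEM) by piecewise-linear Delaunay interpolation, and the
   canopy height model is the per-pixel difference

   `CHM = DSM − DEM`

4. **Inventory.** Zonal statistics of the CHM over each crown polygon
   (count, max, mean, sd, 95th percentile, area) and a per-class summary.
5. **Validation.** Each field-measured stem is matched to the maximum CHM
   value within a 1 m buffer of its GNSS position, and the paired heights go
   through a Pearson correlation test (two-sided, Student *t* with *n* − 2
   degrees of freedom) plus an OLS fit, residual RMSE and mean bias.

Because drone surveys of this kind are rarely deposited, the package also
ships a fully seeded synthetic scene generator (smooth terrain, paraboloid
crowns that are greener than ground, directional crown shadows, sensor
noise, and a GNSS-perturbed field survey restricted to stems with
DBH ≥ 10 cm) that reproduces the statistical structure such a study assumes.
Every synthetic product is a pure function of its configuration and seed.

Rasters are handled by a built-in minimal GeoTIFF codec (uncompressed,
strip-based, float32/uint8/uint16 with the standard georeferencing tags), so
all outputs open directly in QGIS/GDAL tools; crowns are written as GeoJSON
and tables as CSV.

## Worked example

```r
library(forestchm)
library(dplyr)

sim <- simulate_scene(extent = c(0, 0, 60, 60), gsd = 0.1, n_trees = 40,
                      min_spacing = 5, n_field_points = 35, seed = 42)

bands  <- normalize_bands(sim$ortho)
ngbdi  <- compute_index(bands, "NGBDI")
mask   <- reclassify_index(ngbdi, "auto") |> clean_mask(1, 1)
crowns <- extract_crown_polygons(mask) |> (\(cr) classify_crowns(ngbdi, cr))()

surfaces <- surface_set(sim$dsm, mask, seed = 47)   # ground pts -> DEM -> CHM
stats    <- zonal_stats(surfaces$chm, crowns)
inventory_table(stats)
#> # A tibble: 4 × 4
#>   class_label n_crowns mean_height_m total_crown_area_m2
#>         <int>    <int>         <dbl>               <dbl>
#> 1           1        9          16.6                184.
#> 2           2        8          21.2                603.
#> 3           3        9          18.2                307.
#> 4          NA       26          18.6               1095.

fit <- buffer_max_height(surfaces$chm, sim$survey, radius_m = 1) |>
  pearson_test()
fit
#> <chm_validation> n = 35 pairs (0 excluded)
#>   Pearson r = 0.9951, two-sided p = 1.02e-34
#>   field ~ chm: slope = 1.002, intercept = 0.015, rmse = 0.619 m
#>   bias (chm - field) = -0.064 m
```

The 40 trees merge into 26 crown polygons (touching crowns are deliberately
kept as one inventory unit), split into three classes of similar size by
their mean NGBDI; despite 0.10 m GNSS error, 0.5 m field height error,
sensor noise and shadows, the buffered CHM maxima track the field heights
with r ≈ 0.995 and a slope indistinguishable from 1.

`glance(fit)` returns the same summary as a one-row tibble, `tidy(fit)` the
OLS terms, and `autoplot(fit)` draws the field-versus-CHM scatter with the
fitted and 1:1 lines. `run_pipeline(pipeline_config(...))` runs all of the
above (from synthetic or file inputs) and writes every artefact — index and
surface GeoTIFFs, crown GeoJSON, statistics CSVs, a validation JSON and a
`run.log` of all resolved parameters. A thin command-line wrapper lives at
`inst/cli/forestchm.R`.

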