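---
title: "Methods: drone RGB forest inventory with forestchm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drone RGB forest inventory with forestchm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`forestchm` estimates individual-tree heights and crown areas in open
eucalypt forest from two drone-photogrammetry products — an RGB orthomosaic
and a digital surface model (DSM) — and validates the estimates against a
field survey. This vignette is the package's account of the model behind
each stage, the parameters that matter, the numerical conventions that make
the results exactly reproducible, and what the synthetic test bed does and
does not demonstrate.

## The model

The analysis assumes a single map product: all rasters share one projected,
metre-unit grid, and rasters with differing transforms are rejected rather
than silently resampled. Pixel (1, 1) is the top-left cell, a pixel's map
coordinate is its centre, and y decreases with row — the dominant
geospatial raster convention, chosen so that zonal and buffer tests can be
stated exactly.

**Spectral separation.** Raw digital numbers are normalised to fractions
$r = R/(R+G+B)$, $g$, $b$, which sum to one at every valid pixel and cancel
overall illumination. The twelve supported colour indices are algebraic
functions of these fractions; three identities are worth knowing because
the test suite leans on them: $ExGR = ExG - ExR$, $GLA = ExG/(1+g)$ for
normalised bands (since $2g + r + b = 1 + g$), and
$MGRVI = 2\,NGRDI/(1 + NGRDI^2)$. The default masking index is the
green–blue normalised difference $NGBDI = (g-b)/(g+b)$: live crowns have
$g > b$ while bare ground, dry grass and shadow have $g \le b$, so the index
is bimodal over a forest scene. `index_separability()` ranks all twelve
indices by Fisher separability against a reference mask for scenes where a
different index might do better.

**Crown extraction.** The index raster is thresholded; where no threshold
is supplied, Otsu's method on a 256-bin histogram over the observed value
range stands in for choosing a break by eye, and the value used is recorded.
The mask is closed with a disc (default radius 1 px) and patches below
1 m² are dropped — well below the smallest plausible crown (a 10 m tree at
crown ratio 0.15 has ≈ 7 m² of crown), so only speckle is removed.
Components are 8-connected; touching crowns are deliberately *not* split by
watershed or similar: each connected vegetated region is one inventory
unit, and per-tree separation inside merged canopy is out of scope.

**Canopy height.** Ground elevation is only observed where the mask says
"ground"; the DSM value at those pixels *is* the ground (there is no
separate ground survey). Random ground pixels are sampled uniformly without
replacement — default density one point per 25 m², i.e. ~400 points on the
reference scene, enough for a stable triangulation while staying far
sparser than the raster. The DEM is piecewise-linear interpolation on the
Delaunay triangulation of those points (the method is a package decision;
it is parameter-free and exactly reproduces planar surfaces, which gives a
sharp correctness test), with pixels outside the convex hull filled by the
nearest point's value. Then $CHM = DSM - DEM$ per pixel; negative values
are clamped to zero by default (heights are physical) and the clamped-pixel
count is reported so the clamping is never silent.

**Inventory and validation.** A pixel belongs to a crown iff its centre
lies inside the polygon (even-odd rule over exterior and hole rings,
boundary counting as inside); the same centre-distance convention drives
the validation buffer, so there is exactly one membership rule in the
package and both are testable against brute-force scans. Percentiles use
linear interpolation between order statistics (`quantile` type 7). Field
stems are matched to the CHM purely spatially — the maximum CHM value
within 1 m of the recorded position; the buffer absorbs GNSS error of up to
~0.1 m and needs no stem-to-crown identity assignment. The paired heights
feed a hand-computed Pearson test: $r$ from the centred sums,
$t = r\sqrt{(n-2)/(1-r^2)}$, two-sided $p$ from the Student $t$ CDF with
$n-2$ degrees of freedom, $p = 0$ at $|r| = 1$. Alongside $r$ the package
reports the OLS fit of field height on CHM height, the residual RMSE of
that fit, and the mean bias $\overline{chm - field}$.

## The synthetic scene

No drone or field data are distributed with the package, so a seeded
generator emulates the study conditions the analysis assumes. Its defaults
are fixed and are the package's reference conditions:

| parameter | default | why |
|---|---|---|
| extent, GSD | 100 × 100 m at 0.10 m | a stand of ~10⁶ pixels, desk-scale |
| trees | 120, heights uniform 10–30 m | open subtropical eucalypt stand |
| crown ratio | 0.15 m radius per m height | keeps crowns mostly, not fully, separate |
| min stem spacing | 5 m | hard-core placement; some crowns merge, as in real canopy |
| terrain | ±3 m relief, 30 m correlation length | gentle grazing-country topography |
| DBH | 2.0 cm per m height | DBH only feeds the ≥ 10 cm survey inclusion rule |
| survey | 116 points, 0.10 m GNSS sd, 0.5 m height sd | a realistic differential-GNSS field campaign |
| sensor noise | sd 8 DN per band | visible but not dominant speckle |
| shadow | 30 % of each crown's southern border | shadow as a nuisance factor, not a radiometric model |

Crowns are paraboloids of revolution over the stem,
$z(d) = z_{ground}(stem) + h(1 - (d/r_c)^2)$, and the DSM is the pixelwise
maximum of terrain and all crown surfaces. The paraboloid is chosen because
its apex equals the tree height exactly: the discretisation error of the
apex at pixel centres is bounded by $h\,(gsd/(\sqrt{2}r_c))^2$ (< 1 cm at
default settings), which turns height recovery into a quantitative test
rather than a qualitative one. The orthomosaic is rendered from the same
z-buffer that builds the DSM, so a pixel's colour, its DSM ownership and
the truth footprint map agree exactly — on a noise-free scene the
vegetation mask must equal the truth footprints pixel for pixel, and the
suite asserts that it does. Terrain is Gaussian-smoothed white noise
rescaled so the elevation range never exceeds twice the relief amplitude.

What the generator does *not* emulate: radiometric realism (BRDF,
vignetting, colour balance seams), structure-from-motion artefacts (doming,
smearing at occlusions), understorey vegetation that is green but not
canopy, and dense closed canopy with heavily interlocking crowns. Passing
tests therefore show the pipeline's algorithmic correctness and its
robustness to position error, measurement error, additive sensor noise and
border shadow — not performance on degraded photogrammetry or rainforest
structure.

## Numerical conventions

- Index denominators within 1e−12 of zero yield nodata, never infinities
  (WI at $r = g$, VARI at $g + r = b$), so thresholding stages see only
  finite values.
- Rasters are written as float32 GeoTIFF with nodata sentinel −9999;
  `as_float32()` applies the same rounding in memory so round-trip tests
  are bit-exact.
- Crown boundaries are traced on pixel edges, so an unsimplified polygon's
  area equals pixel count × pixel area exactly; Douglas–Peucker
  simplification (default tolerance 2 × GSD) changes the area by at most
  perimeter × tolerance. At corners where two pixels of one 8-connected
  component touch only diagonally, the trace takes the leftmost turn,
  keeping the component a single self-touching, non-crossing ring.
- Crown class breaks are equal-count quantiles of the per-crown mean index
  (type 7); ties at a break go to the lower class, so identical crowns all
  land in class 1.
- The master seed fans out to fixed per-stage offsets (terrain +1, trees
  +2, rendering +3, survey +4, ground points +5), giving stage-level
  reproducibility without user seed bookkeeping; all stochastic stages
  restore the caller's RNG state.

## Problem sizes used by the checks

The test suite exercises oracle comparisons (brute-force all-pixel zonal
and buffer scans, an independent Delaunay/barycentric DEM oracle, the
`cor.test` reference for p-values) on grids of a few thousand pixels, and
runs the full pipeline twice on the 10⁶-pixel reference scene — once
noise-free for height recovery (per-crown maxima within the apex +
measured-DEM error bound for ≥ 95 % of crowns, r ≥ 0.99 against an
error-free survey) and once with all error sources on for the significance
analogue (p < 10⁻⁴ at n = 116). The acceptance script reruns the noisy
experiment from scratch at whatever seed it is given.

## Limitations

Merged crowns report the height of their tallest member; the DEM is least
accurate under large merged canopies and outside the ground-point convex
hull (the hull margin is nearest-filled); the three crown classes are a
spectral partition, not species identification; and heights, not biomass or
DBH, are the deliverable — allometric modelling sits outside the package.
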