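---
title: "Methods: pesticide use and habitat quality around apiary sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pesticide use and habitat quality around apiary sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beescape)
```

## The problem

Commercial beekeeping in grassland-dominated agricultural landscapes faces
two coupled threats: conversion of grassland, wetland and forest (the
forage base) to cropland, and insecticide applications on that cropland
which can drift into the remaining natural covers where bees forage.
`beescape` models both threats jointly around registered apiary (bee yard)
locations: it apportions county-level insecticide-use estimates to
crop-specific district application rates, totals use within the bees' core
foraging range, screens for temporal trends, and converts application
rates into a spatial habitat-degradation and quality model whose per-site
indices separate the land-cover effect from the pesticide effect.

Because the real inputs (annual 30-m land-cover rasters, county pesticide
estimates, a state apiary registry) are large external datasets, the
package ships a first-class synthetic generator that emulates their
statistical structure with known ground truth, so every stage is testable
offline.

## Foraging buffers and the fixed QI denominator

Each apiary site gets a 1609-m (1.6-km, one mile) circular buffer — the
core flight range of foraging honey bees. On the 30-m analysis grid the
buffer is rasterized by the pixel-center rule: a cell belongs to the
buffer iff its center falls inside the buffer polygon.

The site Quality Index uses a *fixed* denominator of 9018 pixels, the
count for an interior buffer. A pixel-center count against an exact
circle of radius 1609 m gives 9033 cells, and no 4-fold-symmetric shape
can give 9018 (symmetric lattice counts are ≡ 1 mod 4, and 9018 ≡ 2),
which indicates the constant originates from a GIS polygonal buffer
approximation. We therefore calibrated, once, an inscribed regular
polygon: 69 segments with the first vertex rotated by 0.2 of one segment
yields exactly 9018 cells for a site at any cell center. The segment
count and rotation are frozen package constants; the count's
translation-invariance on the lattice is tested.

Buffers overlapping the grid edge simply contain fewer cells; the QI
keeps the 9018 denominator as the index defines (an edge-truncated
buffer is genuinely poorer in accessible forage). The synthetic apiary
generator therefore prefers placing sites at least one radius from the
edge, falling back to the whole extent only when the grid is too small.

The reported single-buffer area of ~314 ha in the source material is
inconsistent with a 1609-m radius (9018 × 0.09 ha ≈ 811.6 ha ≈ πr²); we
follow the 9018-pixel/1609-m definition and treat 314 ha as a typo, as
the specification of this pipeline directs.

## Pesticide apportionment and trends

District application rates follow

$$AP_{i,j,d,t} = \frac{\left(\sum_{n=1}^{N_d} Cnty_{i,n,t}\right)\,
ratio_{i,j,t}}{Area_{j,d,t}}$$

with $Cnty$ the county low use estimate (kg), $ratio$ the statewide
pesticide-crop use fraction and $Area$ the district planted area (ha).
Buffer totals are $TP_{i,t} = \sum_{j,d} AP_{i,j,d,t}\, BF_{j,d,t}$ with
$BF$ the non-organic crop area inside the *dissolved* union of all
buffers (union so overlapping buffers are counted once). Low estimates
are used for both the county totals and the ratios; high estimates are
accepted but never mixed.

Trends are ordinary least squares of annual totals on the year, with
zero-use years treated as missing and at least three nonzero years
required. Significance is two-sided at α = 0.05 (a conventional default;
the level is an explicit argument and echoed in the output). Slopes are
kg/yr and independent of the year origin; intercepts are
origin-dependent and reported as fitted.

## Threat layers and risk quotients

Only foliar (spray) insecticides are modelled as drift threats; the
seed-treated neonicotinoids are kept in the trend analysis but refused
as threat layers. Per compound × crop, the threat raster carries the
district application rate max-normalized to [0, 1] across districts on
the non-organic pixels of that crop, zero elsewhere. Organic fields are
exempt from applications (hence from threat and from $BF$) but remain
cropland for habitat scoring — exemption from spraying does not make a
field forage.

Compound weights come from risk quotients RQ = dose / LD50, with the
field rate converted to a per-bee dose by a fixed screening constant
(2.7 µg/bee per lb a.i./acre ≈ 2.409 µg/bee per kg/ha, a Bee-REX style
convention). Oral and contact routes are combined conservatively by the
maximum (configurable to either route alone). Weights are
max-normalized, so the most hazardous compound has weight 1 and the
absolute dose constant cancels; results depend only on toxicity ratios.
The shipped LD50 values are representative published honey-bee acute
toxicities for the four foliar compounds, and are documented as such.

## The degradation and quality model

Threat drifts from treated pixels with an exponential kernel truncated
at $d_{max}$ = 60 m (three 30-m pixels): factor
$\exp(-(\lambda/d_{max})\,d)$ with $\lambda = -\ln 0.05 \approx 2.996$,
so exactly 95% of spray material deposits within $d_{max}$ and the
residual at the cutoff is 5%. (The commonly quoted coefficient 2.99 is
this value rounded; with 2.99 the deposited fraction would be 94.97%,
just under the stated 95%, so the package uses the exact form.)

Degradation at pixel $x$ is

$$D_x = S_x \sum_r \frac{w_r}{\sum_r w_r} \cdot
\frac{\sum_y r_y\, f(d_{xy})}{K}$$

over threat pixels $y$ within $d_{max}$, where $K$ is the truncated
kernel's total mass over the 13-cell neighborhood (including the center
offset). The normalization makes $D = 1$ when every cell in range
carries full threat from every layer, so $D \in [0,1]$ for intensities
in [0, 1]. Sensitivity $S$ equals the 0/1 habitat score: cropland is
habitat 0, natural covers (grassland, herbaceous wetland, forest) are
habitat 1; "bee-friendly" specialty crops are intentionally not modelled
and score 0 like other cropland. Accessibility modifiers are not used.

Note one structural property: $D$ is a weighted *average* across threat
layers (InVEST semantics). Adding a new weighted layer renormalizes the
average, so it can lower $D$ at pixels far from the new layer — quality
is monotone in threat intensity and in threat coverage, but not in the
number of layers. The tests assert the defensible monotonicities and
the average structure explicitly.

Quality applies the half-saturation transform
$Q_x = H_x\,(1 - D_x^z/(D_x^z + k^z))$ with the exponent fixed at
$z = 2.5$ and half-saturation $k = 0.5$ by default ($Q = H/2$ at
$D = k$). The source analysis names the model version but not its $k$;
absolute quality levels are therefore not comparable to the original
study's means, only the model's structural behavior is — which is what
the acceptance suite checks. Both constants are arguments and are echoed
into the run manifest.

The optimized implementation accumulates the 13-offset kernel by matrix
shifts; a brute-force double loop over all pixel pairs within 60 m
serves as the independent oracle in the tests (agreement to 1e-9).

## Site indices

$$QI_{s,t} = \frac{\sum_{p \in \text{buffer}(s)} Q_{p,t}}{9018}, \qquad
DI_{s,t} = \frac{\sum_{g \in \text{natural}(s)} (1 - Q_{g,t})}
{\#\,\text{natural}(s)}$$

QI mixes forage amount and degradation; DI isolates the pesticide effect
on whatever natural cover is present. Indices are computed per site even
where buffers overlap (the dissolved footprint is used only for mass
totals). For an interior site the two are linked by the identity
$QI = (n_{natural}/9018)(1 - DI)$, asserted to 1e-12 in the tests.

Sites whose buffer has no natural pixels get a missing DI (not 0 or 1)
and are excluded from DI summaries with a logged count — zero-filling
would conflate "no forage left" with "no degradation". Yearly summaries
report the mean, a normal-approximation 95% CI halfwidth
(1.96·sd/√n), and percent change against a reference year.

## The synthetic world

The generator's defaults are the stated world and are not tuned:

- **Landscape**: 200×200 cells at 30 m. Class proportions (grassland
  0.40, corn 0.15, soybeans 0.15, wheat 0.10, wetland 0.08, forest and
  other crops 0.06 each) reflect a grassland-dominant mixed agricultural
  region. Patches arise from thresholding a box-smoothed Gaussian random
  field at the rank quantiles of the cumulative proportions, which makes
  realized fractions exact up to rounding while producing contiguous
  field- and prairie-like patches; `patch_scale` (5 cells) sets their
  size.
- **Conversion**: 4% of the initial grassland per elapsed year, matching
  the magnitude of grassland loss over the 2006–2014 window the analysis
  targets. Default mode converts whole patches largest-first (parcel
  conversion); a random-pixel mode represents dispersed expansion.
  Patch-mode conversion removes entire patches *including their degraded
  edges*, so mean DI need not rise monotonically under it even as QI
  falls — a real property of the model worth knowing. The directional
  acceptance check of the joint mechanism (QI falls, DI rises) uses the
  random-pixel mode, whose edge creation mirrors the reported
  boundary-degradation phenomenon.
- **Use tables**: statewide totals follow configured lines with slopes
  equal to the reported trend magnitudes (e.g. Chlorpyrifos 8867.2,
  Clothianidin 1329.9 kg/yr) over 2001–2014, split across 9 counties in
  3 districts by fixed seeded shares, with per-county Gaussian noise
  (sd 300 kg) truncated at zero. With zero noise the summed series
  recovers the configured slope exactly (tested to 1e-9). The statewide
  line, not each county's series, carries the configured slope —
  otherwise summing counties would multiply it.
- **What it does not emulate**: real geography, weather or economics of
  conversion, within-year application timing, spray-day wind, or
  environmental fate. A green test establishes the pipeline's arithmetic
  and structural behavior, not field-validated exposure.

All generators are pure functions of (config, year): the same seed gives
bit-identical outputs, which the pipeline test verifies at the file-byte
level.

## Numerical choices and degenerate inputs

- Pixel membership everywhere is by pixel center; distances are
  Euclidean meters between cell centers in a single local projected CRS
  (mixed geometries are refused, not silently reprojected).
- Categorical resampling to 30 m is nearest-neighbor on centers (any
  averaging would invent classes); the choice is ours, the source does
  not state one.
- Unmapped land-cover codes become nodata (-999) with a logged count;
  missing pesticide-crop ratios contribute 0 with a logged count; a zero
  planted area facing nonzero use is an error rather than an Inf rate.
- Conversion quotas beyond the available grassland convert everything
  with a warning; fewer than three nonzero years make a trend "not
  estimable" rather than a fit.
- Rasters are exchanged as plain-text ESRI ASCII grids and vectors as
  GeoJSON, keeping runs diffable and the package free of binary formats.

## Known limitations

Absolute QI/DI levels depend on the unpublished half-saturation constant
and on relative (max-normalized) threat intensities, so only
within-model comparisons across years and scenarios are meaningful. The
LD50 table is a representative stand-in, adequate because only ratios
matter downstream. District-level apportionment inherits the coarseness
of the underlying survey estimates; rates are not field-level exposure.
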