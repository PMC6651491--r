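---
title: "Dasymetric population mapping and park green-space equity: methods"
author: "parkEquity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dasymetric population mapping and park green-space equity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkEquity)
```

# The problem

Census populations are published per administrative zone (block or
street). Using them directly to measure who can reach an urban park
assumes people are spread evenly inside each zone, and any statistic
computed from them inherits the modifiable areal unit problem. This
package spatializes zone populations onto a fine analysis grid using land
cover as the ancillary variable, computes the walking-time service area of
park entrances over the road network, and overlays the two to count the
population outside a walking-time budget — per cell and per street.

# The dasymetric model

The core assumption is that each land-cover class carries a
characteristic population density. With `p_i` the census count of zone
`i`, `S_ij` the area (m²) of class `j` inside zone `i`, and `a_j` the
density (persons/m²) of class `j`:

```
p_i = sum_j a_j * S_ij           (no intercept: no land, no population)
```

The densities are estimated by regression and then corrected so the
model reproduces each zone's census count exactly:

```
a'_ij = (p_i / p'_i) * a_ij      with p'_i the model prediction
```

After this rescaling the inversion onto the analysis grid,

```
pop_k = sum_i sum_j a'_ij * s_ijk
```

with `s_ijk` the class-j area of zone i inside analysis cell k, is
mass-preserving (pycnophylactic): cell values sum back to every zone
total, and the grid total equals the census total. `rescaleCoefficients()`
and `gridPopulation()` implement these steps; the package asserts the
conservation identities to 1e-6 relative tolerance in its tests and
reproduces block totals to machine precision.

Zones predicted at zero density but carrying population fall back to a
uniform density over their non-excluded area, which keeps the correction
exact; the water class can be excluded from that fallback.

## Global versus local coefficients

`fitOLS()` estimates one `a_j` per class. Population density is spatially
non-stationary, so `fitGWR()` estimates a local coefficient vector at
every zone centroid by weighted least squares with an adaptive bisquare
kernel,

```
w_ij = (1 - (d_ij / b_i)^2)^2 for d_ij < b_i, else 0
```

where `b_i` is the distance to the bandwidth-th nearest neighbour. The
kernel family is the standard adaptive choice in the GWR literature; a
uniform kernel is provided mainly because at full bandwidth it reproduces
the global fit exactly, which the tests exploit. The bandwidth (a
neighbour count) is chosen by exhaustive minimisation of the corrected
information criterion

```
AICc = n log(RSS/n) + n log(2 pi) + n (n + tr(S)) / (n - 2 - tr(S))
```

with `tr(S)` the hat-matrix trace (effective parameters). Ties break
toward the larger, smoother bandwidth, and bandwidths whose local design
is singular at any zone are treated as infeasible. The search ladder is
exhaustive rather than a golden-section refinement: at the problem sizes
this package targets (tens to hundreds of zones) the full ladder costs
seconds and is deterministic.

Both models are fitted without an intercept by default, which is the
dasymetric constraint; a local intercept can be restored with
`noIntercept = FALSE`, but such a fit cannot be converted to a
coefficient field (an intercept has no area to spread over). Negative
fitted densities are clamped to zero before dasymetric use (configurable)
— they violate the model's premise and would corrupt the rescaling.

## Model comparison

`compareModels()` reports the adjusted R² of both fits, the AIC
difference with the rule that only a gap larger than 3 distinguishes the
models, and the spatial autocorrelation of each model's residuals
(`moranI()`, expectation −1/(n−1), randomization variance, optional
permutation null). One numerical subtlety: the plain Gaussian OLS AIC
`n log(RSS/n) + 2(k+1)` and the GWR AICc differ by the constant
`n log(2π)` plus the finite-sample correction, so differencing them
directly would always favour one side regardless of fit. The comparison
therefore recomputes the global model's criterion in the same corrected
form (its hat trace is exactly `k`), so two models with identical
residuals and equal effective parameters tie exactly.

R² for both models is defined against the centred total sum of squares,
including in no-intercept mode, so the global and local values are on one
scale. Variance inflation factors come from intercept-bearing auxiliary
regressions among the predictors, the textbook definition.

Moran's I weights default to row-standardized inverse distance between
zone centroids — fully general and the default of the common desktop GIS
implementation. Queen contiguity is available; it is derived from
bounding-box touch tests, which is exact for the rectangular zone
tessellations the generator produces but approximate for concave
polygons (a documented limitation).

# Accessibility

`buildNetwork()` turns noded road segments into an undirected graph with
edge traversal times `length / (speed * 60)` minutes; walking speed
defaults to 1 m/s. Nodes of degree ≥ 3 are intersections and carry a
0.5-minute crossing delay, charged when a path passes *through* them —
not at the origin (the walker starts there) nor at the terminal node (no
crossing happens). This is implemented by a directed reformulation in
which each directed edge carries its head node's delay, after which the
terminal charge is subtracted; the exhaustive path-enumeration oracle in
the tests verifies the rule end to end. Park entrances snap to the
nearest node within 100 m or are inserted by splitting the nearest edge.

`serviceArea()` runs multi-source shortest paths from all entrances
(threshold 15 minutes by default). `gridCoverage()` maps node times onto
the analysis grid: a cell's time is the nearest node's arrival time plus
straight-line walking from the cell centre to that node, with cells more
than 500 m from the network flagged unserved. Nearest-node snapping is
the simplest defensible off-network rule; it slightly overestimates
travel time relative to a nearest-edge projection (an alternative
interpretation, not currently implemented) and makes the covered set
reproducible cell by cell.

# Equity overlay

`overlayCoverage()` masks the population grid with the coverage flags to
produce the low-accessibility surface and the headline totals (covered
population and area, and their percentages). `streetEquity()` aggregates
both surfaces per street by cell centre — the same areal convention used
for raster-to-zone assignment, so population is counted exactly once
everywhere. Fully covered streets are classed "equitable"; the remainder
are binned by uncovered population at the quartiles of the nonzero
counts by default, since no canonical bin edges exist for these labels;
explicit thresholds can be supplied.

# The synthetic city

`generateCity()` produces the validation inputs. The default
configuration — the package's study conditions — is a 150 × 144 cell,
30 m land-cover raster (4.5 × 4.32 km) with the seven urban classes
(woodland, farmland, water, road, bare land, factory, other paving) at
shares 15/10/10/12/8/10/35%, 90 rectangular census blocks (10 × 9), a
300 m road lattice with 15% of edges removed (connectivity preserved, so
missing links create detours), and 6 park entrances on road nodes. Block
populations follow the generating equation with per-class densities
(0.0008, 0.0004, 0, 0.006, 0.001, 0.004, 0.018 persons/m²; e.g. other
paving ≈ 18,000 persons per km² of paved residential fabric — plausible
dense-urban magnitudes, with water fixed at zero) plus additive Gaussian
block noise with a 150-person standard deviation (roughly 5–10% of a
typical block), clamped at zero because populations are counts.

Land cover is built from seeded multi-scale value noise thresholded at
the class-proportion quantiles, which yields contiguous patches with
realistic spatial autocorrelation; i.i.d. cell labels would make the
local regression unrealistically easy. What the generator does *not*
emulate: irregular zone geometry, multi-storey population (density
varies vertically in real cities), classification error correlated with
class boundaries, and road networks with curved geometry. Passing tests
therefore demonstrate correctness of the estimators and bookkeeping
under the stated statistical structure, not predictive skill on real
imagery-derived inputs.

## The parameter-recovery study

Two designed experiments validate estimation:

* constant densities, zero noise: the global no-intercept fit must
  return the generating coefficients to numerical precision (the design
  matrix is well conditioned and the system is exactly consistent);
* smooth linear-gradient density surfaces, zero noise: local estimates
  must correlate with the generating surface (r > 0.9 per class), the
  local model must beat the global one on adjusted R², and its residuals
  must be closer to spatial randomness.

The gradient study uses 3 classes over 210 blocks rather than the
default 7 over 90. Class areas are compositional (they sum to the block
area), so with many classes the local fits are individually
weakly identified even at zero noise — estimates of the small-share,
small-coefficient classes trade off against each other inside a kernel
window while the fitted surface is essentially unchanged. Three classes
with substantial shares and clearly separated gradients make every local
coefficient identifiable, which is what a recovery experiment requires.
This is a property of the design, not of the estimator.

# Numerical choices and degenerate inputs

* Cell-to-zone and cell-to-street assignment is by cell centre, first
  matching polygon; this conserves areas exactly (no sliver geometry)
  and makes every split identity (`sum_k s_ijk = S_ij`) hold to the last
  bit. The analysis grid is anchored at the raster origin and its cell
  size must be an integer multiple of the raster's, enforced with an
  instruction to resample otherwise.
* Nodata raster cells are excluded from every area sum (masking
  mechanism for zones without usable data).
* Spearman p-values use the large-sample t approximation; zero-variance
  classes are reported missing with a warning rather than failing the
  screen.
* Perfectly collinear predictors abort the global fit naming the
  offending classes; duplicate centroids abort adaptive weighting.
* Chance-agreement kappa is exactly 0 by construction; the degenerate
  single-label, perfect-agreement case defines kappa = 1.
* All generators and permutation tests are seeded; identical
  configuration and seed give byte-identical outputs, which the test
  suite asserts on the written CSV files.

Problem sizes in the shipped validation runs — 90 or 210 zones, 21,600
raster cells, ~870 analysis cells, road graphs of a few hundred nodes —
were chosen so the whole suite and the acceptance script each complete
in well under a minute while exercising every code path at realistic
urban extents.

# Worked example

```{r example, eval = FALSE}
city <- generateCity(cityConfig(seed = 1))
res <- runPipeline(city@landCover, city@zones, city@roads,
                   city@parkEntrances,
                   config = pipelineConfig(regression = "gwr"))
res$comparison   # OLS vs GWR diagnostics
res$errors       # relative-error table before rescaling
res$report       # coverage totals and street-scale equity
```

# Known limitations

* Zone-constant application of local coefficients: the coefficient at a
  zone's centroid applies uniformly within the zone (no within-zone
  coefficient interpolation), which keeps the rescaling well defined.
* No semi-parametric or multiscale GWR; no heteroscedasticity-robust
  errors.
* Queen contiguity is bounding-box based (exact only for rectangular
  tessellations).
* Walking only: no cycling/transit modes, turn restrictions, or
  time-of-day effects; no continuous along-edge isochrone
  interpolation.
* Rasters are read and written as ESRI ASCII grids with a JSON class
  sidecar, and vectors as GeoJSON in a projected metre frame.
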