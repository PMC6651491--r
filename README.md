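# parkEquity

Who lives beyond a 15-minute walk of an urban park? Answering that from
census data alone is unreliable: populations are published per
administrative zone and are anything but uniform inside one. `parkEquity`
implements the full analysis chain used in green-space equity studies:

1. **Dasymetric population mapping.** Zone populations are regressed on
   per-class land-cover areas, `p_i = Σ_j a_j S_ij` (no intercept — no
   land, no population), with the density coefficients `a_j` estimated
   either globally (OLS) or locally by **geographically weighted
   regression** (adaptive bisquare kernel, bandwidth by minimum AICc).
   Coefficients are then rescaled per zone, `a'_ij = (p_i / p'_i) a_j`,
   so every census total is reproduced exactly, and population is
   inverted onto a fine grid, `pop_k = Σ_ij a'_ij s_ijk` (150 m cells by
   default). The inversion is mass-preserving: the grid sums back to the
   census.
2. **Network accessibility.** Roads become a walking-time graph (1 m/s;
   0.5 min per interior intersection crossed). Multi-source shortest
   paths from the park entrances give each node's arrival time, mapped
   onto the grid; cells within 15 minutes are covered.
3. **Equity overlay.** Masking the population grid with the coverage
   mask yields the low-accessibility population surface, city-level
   totals (covered population and area, with percentages) and
   street-scale statistics with equity classes.

Model diagnostics follow standard practice: Spearman screening of
candidate classes, VIF, adjusted R², AIC comparison with a
3-point-difference rule, and global Moran's I of the residuals
(randomization inference, optional permutation null).

A first-class synthetic-city generator (`generateCity()`) produces land
cover with contiguous patches, blocks whose populations follow the
generating equation with known ground-truth coefficients, a gappy road
lattice and park entrances — so every stage is testable against
closed-form or brute-force oracles and parameter recovery is measurable.

## Worked example

```r
library(parkEquity)
city <- generateCity(cityConfig(seed = 1))   # the default study city
res <- runPipeline(city@landCover, city@zones, city@roads,
                   city@parkEntrances,
                   config = pipelineConfig(regression = "gwr"))
res$comparison
#> Model comparison: delta AIC (OLS - GWR) = -6.131 -> ols
#>   adj R2: OLS 0.978, GWR 0.978
#>   residual Moran's I: OLS -0.0141 (p 0.803), GWR -0.0195 (p 0.469)
res$errors
#> ErrorReport: mean |relative error| 22.6% over 90 zones
#>   |E| bins: <=10%: 55, 10-20%: 20, 20-30%: 4, >30%: 11
res$report
#> EquityReport: 15.6% of population covered (23052 of 147536 persons)
#>   covered area 4.162 km^2 (21.3% of study area)
#>   90 streets, 6 fully covered (equitable)
head(res$report@streets[order(-res$report@streets$uncovered), ], 3)
#>    street_id population uncovered coverage_pct             class
#> 30    B10_03   4905.938  4905.938            0 extremely unequal
#> 26    B06_03   4312.103  4312.103            0 extremely unequal
#> 24    B04_03   4207.489  4207.489            0 extremely unequal
```

Reading the output: the default city has spatially constant true
densities, so the local model cannot beat the global one — the AIC gap is
small and both adjusted R² agree, with residuals indistinguishable from
spatial randomness (that is the correct answer here; under a spatially
varying density surface GWR wins decisively, as the test suite shows).
Before rescaling, the block-level predictions are off by 22.6% on
average — exactly the error the mass-preserving correction then removes.
The equity report says 15.6% of residents live within a 15-minute walk of
one of the six park entrances, covering 21.3% of the study area; the
street table ranks streets by their excluded population.

A command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R --synth-seed 1 --out demo_out/
Rscript inst/scripts/run_pipeline.R --landcover lc.asc --zones z.geojson \
    --roads r.geojson --parks p.geojson --config cfg.yaml --out out/
```

Inputs are a categorical land-cover raster (ESRI ASCII grid + JSON class
sidecar), zone polygons with a `population` property (GeoJSON), road
LineStrings (GeoJSON) and park-entrance points (GeoJSON), all in one
projected metre coordinate frame.

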