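Package: parkEquity
Title: Dasymetric Population Mapping and Park Green-Space Equity Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to evaluate the spatial equity of urban park green space
    at sub-district scale. Block-level census populations are spatialized
    onto a fine analysis grid with a land-cover dasymetric model whose
    per-class density coefficients are estimated by ordinary least squares
    or geographically weighted regression (adaptive bisquare kernel,
    AICc bandwidth selection), rescaled to preserve block totals.
    Walking-time service areas of park entrances are computed over a road
    network with per-intersection delay, and the two surfaces are overlaid
    to quantify the population outside a walking-time threshold, summarised
    per street. A synthetic-city generator provides inputs with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessibility.R'
    'dasymetric.R'
    'equity.R'
    'io.R'
    'landcover-stats.R'
    'moran.R'
    'pipeline.R'
    'population-model.R'
    'synthetic-city.R'
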