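#' @import methods
NULL

#' Analysis grid definition
#'
#' Describes a regular square-cell grid in a projected (metre) coordinate
#' frame. The origin is the outer corner of cell (1, 1), i.e. the top-left
#' corner of the grid; rows increase downwards (decreasing y), columns
#' increase with x.
#'
#' @slot cellSize numeric(1), cell edge length in metres.
#' @slot origin numeric(2), (x, y) of the top-left outer corner.
#' @slot nrow,ncol integer(1), grid dimensions in cells.
#' @exportClass GridDefinition
setClass("GridDefinition",
    representation(cellSize = "numeric", origin = "numeric",
                   nrow = "integer", ncol = "integer"))

setValidity("GridDefinition", function(object) {
    msg <- NULL
    if (length(object@cellSize) != 1 || object@cellSize <= 0)
        msg <- c(msg, "cellSize must be a single positive number")
    if (length(object@origin) != 2 || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be two finite coordinates")
    if (object@nrow < 1L || object@ncol < 1L)
        msg <- c(msg, "grid dimensions must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Categorical land-cover raster
#'
#' Integer-coded land-cover classes on a regular grid. Cell (1, 1) sits at
#' the top-left; each cell covers cellSize^2 square metres. Cells holding
#' the nodata code are excluded from every area statistic.
#'
#' @slot codes integer matrix of class codes.
#' @slot cellSize numeric(1), metres.
#' @slot origin numeric(2), (x, y) of the top-left outer corner.
#' @slot classLabels named character; names are class codes as strings.
#' @slot nodataCode integer(1).
#' @exportClass LandCoverRaster
setClass("LandCoverRaster",
    representation(codes = "matrix", cellSize = "numeric",
                   origin = "numeric", classLabels = "character",
                   nodataCode = "integer"))

setValidity("LandCoverRaster", function(object) {
    msg <- NULL
    if (length(object@cellSize) != 1 || object@cellSize <= 0)
        msg <- c(msg, "cellSize must be a single positive number")
    if (!is.integer(object@codes))
        msg <- c(msg, "codes must be an integer matrix")
    used <- setdiff(unique(as.vector(object@codes)), object@nodataCode)
    unlabelled <- setdiff(as.character(used), names(object@classLabels))
    if (length(unlabelled))
        msg <- c(msg, paste0("codes without a class label: ",
                             paste(unlabelled, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' Set of population zones
#'
#' Zones (census blocks or streets) as simple polygons with an observed
#' population count and a representative coordinate (the polygon centroid),
#' the sample point used in the spatial regressions.
#'
#' @slot ids character, unique zone identifiers.
#' @slot polygons list of closed two-column coordinate matrices.
#' @slot population numeric, persons per zone (>= 0).
#' @slot centroids two-column matrix of (u, v) coordinates in metres.
#' @exportClass ZoneSet
setClass("ZoneSet",
    representation(ids = "character", polygons = "list",
                   population = "numeric", centroids = "matrix"))

setValidity("ZoneSet", function(object) {
    msg <- NULL
    n <- length(object@ids)
    if (anyDuplicated(object@ids))
        msg <- c(msg, "zone ids must be unique")
    if (length(object@polygons) != n || length(object@population) != n ||
        nrow(object@centroids) != n)
        msg <- c(msg, "ids, polygons, population and centroids lengths differ")
    if (any(object@population < 0, na.rm = TRUE))
        msg <- c(msg, "populations must be non-negative")
    if (any(!is.finite(object@centroids)))
        msg <- c(msg, "centroids must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Per-zone, per-class area table
#'
#' Areas (m^2) of each land-cover class inside each zone, the S_ij of the
#' dasymetric model. Rows are zones, columns are class codes.
#'
#' @slot areas numeric matrix with zone ids as rownames and class codes as
#'   colnames.
#' @slot emptyZones character, ids of zones that contained no raster cell
#'   centre (their rows are zero).
#' @exportClass ClassAreaTable
setClass("ClassAreaTable",
    representation(areas = "matrix", emptyZones = "character"))

setValidity("ClassAreaTable", function(object) {
    msg <- NULL
    if (any(object@areas < 0)) msg <- c(msg, "areas must be non-negative")
    if (is.null(rownames(object@areas)) || is.null(colnames(object@areas)))
        msg <- c(msg, "areas must carry zone ids (rownames) and class codes (colnames)")
    if (is.null(msg)) TRUE else msg
})

#' Class areas split by analysis-grid cell
#'
#' The s_ijk of the grid inversion: area of class j inside zone i that
#' falls in analysis cell k. Stored long (zone, class, cell, area); the
#' split conserves the per-zone class areas exactly.
#'
#' @slot table data.frame with columns zone (character), class (integer),
#'   cell (integer, row-major analysis-cell index), area (m^2).
#' @slot grid the \linkS4class{GridDefinition} of the analysis grid.
#' @exportClass GridCellAreas
setClass("GridCellAreas",
    representation(table = "data.frame", grid = "GridDefinition"))

#' Dasymetric coefficient field
#'
#' Per-zone, per-class population-density coefficients (persons per m^2):
#' the initial model estimates (a global coefficient replicated over zones
#' for OLS, the local estimate at each zone centroid for GWR) and, after
#' rescaling, the adjusted coefficients that reproduce each zone's census
#' total exactly.
#'
#' @slot initial numeric matrix, zones x classes.
#' @slot adjusted numeric matrix, same shape, or 0-row before rescaling.
#' @slot provenance character(1), which model produced the field.
#' @exportClass CoefficientField
setClass("CoefficientField",
    representation(initial = "matrix", adjusted = "matrix",
                   provenance = "character"),
    prototype(adjusted = matrix(numeric(0), 0, 0), provenance = "unknown"))

setValidity("CoefficientField", function(object) {
    msg <- NULL
    if (is.null(rownames(object@initial)) || is.null(colnames(object@initial)))
        msg <- c(msg, "initial must carry zone ids (rownames) and class codes (colnames)")
    if (nrow(object@adjusted) &&
        !identical(dim(object@adjusted), dim(object@initial)))
        msg <- c(msg, "adjusted must match initial in shape")
    if (is.null(msg)) TRUE else msg
})

#' Gridded population estimate
#'
#' Estimated persons per analysis cell after dasymetric inversion.
#'
#' @slot values numeric matrix of persons per cell (rows x cols of grid).
#' @slot grid the \linkS4class{GridDefinition}.
#' @slot studyMask logical matrix; TRUE for cells that intersect the study
#'   area (received land-cover area from some zone).
#' @exportClass PopulationGrid
setClass("PopulationGrid",
    representation(values = "matrix", grid = "GridDefinition",
                   studyMask = "matrix"))

setValidity("PopulationGrid", function(object) {
    msg <- NULL
    if (!identical(dim(object@values),
                   c(object@grid@nrow, object@grid@ncol)))
        msg <- c(msg, "values shape must match the grid definition")
    if (any(object@values < -1e-9, na.rm = TRUE))
        msg <- c(msg, "cell populations must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Walking-time road network
#'
#' Undirected road graph with per-edge traversal times (minutes) and a
#' fixed delay charged when a walker crosses an intersection (a node of
#' degree >= 3) in the interior of a path. Park entrances are source nodes.
#'
#' @slot graph an igraph object; edge attributes length (m) and time (min).
#' @slot coords two-column matrix of node coordinates (metres).
#' @slot intersection logical, per node: degree >= 3.
#' @slot sources integer, node indices of park entrances.
#' @slot speed numeric(1), walking speed in m/s.
#' @slot penalty numeric(1), per-intersection delay in minutes.
#' @exportClass TravelNetwork
setClass("TravelNetwork",
    representation(graph = "ANY", coords = "matrix",
                   intersection = "logical", sources = "integer",
                   speed = "numeric", penalty = "numeric"))

setValidity("TravelNetwork", function(object) {
    msg <- NULL
    if (object@speed <= 0) msg <- c(msg, "speed must be positive")
    if (object@penalty < 0) msg <- c(msg, "penalty must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Network service-area result (node part)
#'
#' Shortest arrival time (minutes) at every network node from the nearest
#' park entrance, including intersection delays at interior crossings, and
#' the covered flag at the walking-time threshold.
#'
#' @slot times numeric, per-node arrival time (Inf if unreachable).
#' @slot covered logical, times <= threshold.
#' @slot threshold numeric(1), minutes.
#' @exportClass ServiceArea
setClass("ServiceArea",
    representation(times = "numeric", covered = "logical",
                   threshold = "numeric"))

#' Per-cell accessibility coverage
#'
#' Travel time from each analysis-grid cell centre to the nearest park
#' entrance: network arrival time at the nearest node plus straight-line
#' walking from the cell centre to that node.
#'
#' @slot times numeric matrix of minutes (Inf where unreachable).
#' @slot covered logical matrix, total time <= threshold.
#' @slot unserved logical matrix, TRUE where the nearest node is farther
#'   than the off-network limit.
#' @slot grid the \linkS4class{GridDefinition}.
#' @slot threshold numeric(1), minutes.
#' @exportClass CoverageGrid
setClass("CoverageGrid",
    representation(times = "matrix", covered = "matrix",
                   unserved = "matrix", grid = "GridDefinition",
                   threshold = "numeric"))

#' Global OLS fit of population on class areas
#'
#' @slot coefficients named numeric, persons/m^2 per class.
#' @slot intercept numeric(1), 0 in no-intercept mode.
#' @slot residuals,fitted numeric per zone.
#' @slot r2,adjR2,aic numeric(1).
#' @slot vif named numeric, variance inflation factors.
#' @slot predictors character, class codes used.
#' @slot noIntercept logical(1).
#' @exportClass OLSFit
setClass("OLSFit",
    representation(coefficients = "numeric", intercept = "numeric",
                   residuals = "numeric", fitted = "numeric",
                   r2 = "numeric", adjR2 = "numeric", aic = "numeric",
                   vif = "numeric", predictors = "character",
                   noIntercept = "logical"))

#' Geographically weighted regression fit
#'
#' Local coefficients estimated at every zone centroid by distance-weighted
#' least squares under an adaptive kernel.
#'
#' @slot local numeric matrix, zones x predictors (plus "(Intercept)" when
#'   enabled).
#' @slot residuals,fitted numeric per zone.
#' @slot bandwidth integer(1), adaptive neighbour count.
#' @slot kernel character(1).
#' @slot trS numeric(1), trace of the hat matrix (effective parameters).
#' @slot aicc,r2,adjR2 numeric(1).
#' @slot predictors character, class codes used.
#' @slot noIntercept logical(1).
#' @exportClass GWRFit
setClass("GWRFit",
    representation(local = "matrix", residuals = "numeric",
                   fitted = "numeric", bandwidth = "integer",
                   kernel = "character", trS = "numeric", aicc = "numeric",
                   r2 = "numeric", adjR2 = "numeric",
                   predictors = "character", noIntercept = "logical"))

setValidity("GWRFit", function(object) {
    msg <- NULL
    n <- length(object@residuals)
    p <- length(object@predictors) + as.integer(!object@noIntercept)
    if (!is.finite(object@aicc)) msg <- c(msg, "AICc must be finite")
    if (object@trS < p - 1e-6 || object@trS > n + 1e-6)
        msg <- c(msg, "tr(S) must lie between the parameter count and n")
    if (is.null(msg)) TRUE else msg
})

#' Global Moran's I result
#'
#' @slot I numeric(1), the statistic.
#' @slot expected numeric(1), -1/(n-1).
#' @slot variance numeric(1), randomization variance.
#' @slot z,p numeric(1), normal-approximation z-score and two-sided p.
#' @slot scheme character(1), spatial-weight scheme.
#' @slot permutations numeric, permuted I values (length 0 if not requested).
#' @exportClass MoranResult
setClass("MoranResult",
    representation(I = "numeric", expected = "numeric",
                   variance = "numeric", z = "numeric", p = "numeric",
                   scheme = "character", permutations = "numeric"),
    prototype(permutations = numeric(0)))

#' OLS versus GWR comparison
#'
#' Model preference by AIC difference (meaningful only beyond 3) together
#' with the residual spatial-autocorrelation diagnostics of both models.
#'
#' @slot deltaAIC numeric(1), AICc(OLS) - AICc(GWR), both in the corrected
#'   Gaussian form so the difference is comparable.
#' @slot preferred character(1): "ols", "gwr" or "indistinguishable".
#' @slot olsAdjR2,gwrAdjR2 numeric(1).
#' @slot olsMoran,gwrMoran \linkS4class{MoranResult} of the residuals.
#' @exportClass ModelComparison
setClass("ModelComparison",
    representation(deltaAIC = "numeric", preferred = "character",
                   olsAdjR2 = "numeric", gwrAdjR2 = "numeric",
                   olsMoran = "MoranResult", gwrMoran = "MoranResult"))

#' Classification accuracy report
#'
#' @slot confusion square count matrix, rows = reference, cols = predicted.
#' @slot overallAccuracy numeric(1), trace / total.
#' @slot kappa numeric(1), Cohen's kappa.
#' @exportClass AccuracyReport
setClass("AccuracyReport",
    representation(confusion = "matrix", overallAccuracy = "numeric",
                   kappa = "numeric"))

setValidity("AccuracyReport", function(object) {
    msg <- NULL
    if (object@overallAccuracy < 0 || object@overallAccuracy > 1)
        msg <- c(msg, "overall accuracy must lie in [0, 1]")
    if (object@kappa < -1 - 1e-12 || object@kappa > 1 + 1e-12)
        msg <- c(msg, "kappa must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Relative-error report of the dasymetric prediction
#'
#' @slot errors numeric, signed per-zone relative error (%).
#' @slot bins integer, counts of |error| in (<=10, 10-20, 20-30, >30).
#' @slot meanAbs numeric(1), mean absolute relative error (%).
#' @slot undefined character, ids of zones with zero census population.
#' @exportClass ErrorReport
setClass("ErrorReport",
    representation(errors = "numeric", bins = "integer",
                   meanAbs = "numeric", undefined = "character"))

#' Park green-space equity report
#'
#' The overlay of the population grid with the accessibility coverage mask:
#' the low-accessibility population surface, the covered totals, and (when
#' street zones are supplied) per-street statistics with equity classes.
#'
#' @slot lowAccess \linkS4class{PopulationGrid} of uncovered persons per cell.
#' @slot coveredPopulation,uncoveredPopulation numeric(1), persons.
#' @slot coveredFractionPct numeric(1), % of total population covered.
#' @slot coveredAreaKm2 numeric(1), covered study area.
#' @slot areaFractionPct numeric(1), % of study area covered.
#' @slot streets data.frame: street_id, population, uncovered, coverage_pct,
#'   class (empty when streets were not supplied).
#' @exportClass EquityReport
setClass("EquityReport",
    representation(lowAccess = "PopulationGrid",
                   coveredPopulation = "numeric",
                   uncoveredPopulation = "numeric",
                   coveredFractionPct = "numeric",
                   coveredAreaKm2 = "numeric",
                   areaFractionPct = "numeric",
                   streets = "data.frame"))

#' Synthetic-city generator configuration
#'
#' Parameters of the synthetic study region: a multi-class land-cover
#' raster with contiguous patches, rectangular census blocks whose
#' populations follow the dasymetric generating equation
#' p_i = sum_j coef_j(u_i, v_i) * S_ij + noise (clamped at 0), a lattice
#' road network with random gaps, and park entrances on road nodes.
#'
#' @slot rasterWidth,rasterHeight integer, raster size in cells; must be
#'   divisible by nBlocksX / nBlocksY so blocks align to whole cells.
#' @slot cellSize numeric(1), metres.
#' @slot nClasses integer(1).
#' @slot classProportions numeric, target share of each class (sums to 1).
#' @slot patchScale numeric(1), characteristic patch size in cells.
#' @slot nBlocksX,nBlocksY integer(1).
#' @slot trueCoefficients either a numeric vector of length nClasses
#'   (spatially constant persons/m^2) or a list of nClasses functions
#'   f(u, v) returning the local density (>= 0 everywhere).
#' @slot noiseSd numeric(1), sd of additive block-level noise (persons).
#' @slot roadSpacing numeric(1), lattice spacing in metres.
#' @slot edgeDropFraction numeric(1), fraction of lattice edges removed
#'   (connectivity preserved).
#' @slot nParks integer(1), number of park entrances.
#' @slot seed integer(1).
#' @exportClass CityConfig
setClass("CityConfig",
    representation(rasterWidth = "integer", rasterHeight = "integer",
                   cellSize = "numeric", nClasses = "integer",
                   classProportions = "numeric", patchScale = "numeric",
                   nBlocksX = "integer", nBlocksY = "integer",
                   trueCoefficients = "ANY", noiseSd = "numeric",
                   roadSpacing = "numeric", edgeDropFraction = "numeric",
                   nParks = "integer", seed = "integer"))

setValidity("CityConfig", function(object) {
    msg <- NULL
    if (object@cellSize <= 0) msg <- c(msg, "cellSize must be positive")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
    if (any(c(object@rasterWidth, object@rasterHeight, object@nClasses,
              object@nBlocksX, object@nBlocksY, object@nParks) < 1L))
        msg <- c(msg, "all counts must be >= 1")
    if (length(object@classProportions) != object@nClasses ||
        abs(sum(object@classProportions) - 1) > 1e-8)
        msg <- c(msg, "classProportions must have length nClasses and sum to 1")
    if (object@rasterWidth %% object@nBlocksX != 0L ||
        object@rasterHeight %% object@nBlocksY != 0L)
        msg <- c(msg, "raster cannot host the requested blocks: rasterWidth/rasterHeight must be divisible by nBlocksX/nBlocksY")
    tc <- object@trueCoefficients
    if (is.numeric(tc)) {
        if (length(tc) != object@nClasses)
            msg <- c(msg, "trueCoefficients must have one entry per class")
        if (any(tc < 0))
            msg <- c(msg, "densities must be non-negative (no land without population admits zero, not negative)")
    } else if (is.list(tc)) {
        if (length(tc) != object@nClasses || !all(vapply(tc, is.function, TRUE)))
            msg <- c(msg, "trueCoefficients list must hold one function per class")
    } else {
        msg <- c(msg, "trueCoefficients must be a numeric vector or a list of functions")
    }
    if (object@edgeDropFraction < 0 || object@edgeDropFraction >= 1)
        msg <- c(msg, "edgeDropFraction must be in [0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' Synthetic city
#'
#' A complete generated study region: land cover, census blocks, roads,
#' park entrances, and the ground-truth coefficient field that generated
#' the block populations.
#'
#' @slot landCover \linkS4class{LandCoverRaster}.
#' @slot zones \linkS4class{ZoneSet}.
#' @slot roads data.frame of segments: x0, y0, x1, y1, length (m).
#' @slot parkEntrances two-column coordinate matrix (on road nodes).
#' @slot truth \linkS4class{CoefficientField} of generating coefficients.
#' @slot config the \linkS4class{CityConfig} used.
#' @exportClass SyntheticCity
setClass("SyntheticCity",
    representation(landCover = "LandCoverRaster", zones = "ZoneSet",
                   roads = "data.frame", parkEntrances = "matrix",
                   truth = "CoefficientField", config = "CityConfig"))
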