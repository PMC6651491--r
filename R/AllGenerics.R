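#' @include AllClasses.R
NULL

# ---- generics ---------------------------------------------------------------

#' Cell size of a gridded object
#' @param x a gridded object.
#' @return numeric(1), metres.
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' Raster / grid origin (top-left outer corner)
#' @param x a gridded object.
#' @return numeric(2), (x, y) in metres.
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' Class codes present in an object
#' @param x an object carrying land-cover classes.
#' @return character vector of class codes.
#' @export
setGeneric("classCodes", function(x) standardGeneric("classCodes"))

#' Class labels
#' @param x an object carrying land-cover classes.
#' @return named character (code -> label).
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Zone identifiers
#' @param x an object indexed by zones.
#' @return character vector.
#' @export
setGeneric("zoneIds", function(x) standardGeneric("zoneIds"))

#' Observed zone populations
#' @param x a \linkS4class{ZoneSet} (or object containing one).
#' @return numeric vector, persons.
#' @export
setGeneric("zonePopulation", function(x) standardGeneric("zonePopulation"))

#' Zone representative coordinates
#' @param x a \linkS4class{ZoneSet}.
#' @return two-column matrix of (u, v) metres.
#' @export
setGeneric("zoneCentroids", function(x) standardGeneric("zoneCentroids"))

#' Per-zone class-area matrix
#' @param x a \linkS4class{ClassAreaTable}.
#' @return numeric matrix (zones x classes), m^2.
#' @export
setGeneric("classAreas", function(x) standardGeneric("classAreas"))

#' Grid values of a raster-like result
#' @param x a \linkS4class{PopulationGrid} or \linkS4class{CoverageGrid}.
#' @return numeric or logical matrix.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Population density surface
#'
#' Converts persons per analysis cell to persons per km^2
#' (divide by cellSize^2 / 1e6; at 150 m cells the factor is 1/0.0225).
#'
#' @param x a \linkS4class{PopulationGrid}.
#' @return numeric matrix, persons per km^2.
#' @export
setGeneric("densityPerKm2", function(x) standardGeneric("densityPerKm2"))

# ---- accessors --------------------------------------------------------------

#' @describeIn cellSize cell size of a land-cover raster.
#' @export
setMethod("cellSize", "LandCoverRaster", function(x) x@cellSize)
#' @describeIn cellSize cell size of a grid definition.
#' @export
setMethod("cellSize", "GridDefinition", function(x) x@cellSize)
#' @describeIn cellSize analysis-cell size of a population grid.
#' @export
setMethod("cellSize", "PopulationGrid", function(x) x@grid@cellSize)

#' @describeIn gridOrigin origin of a land-cover raster.
#' @export
setMethod("gridOrigin", "LandCoverRaster", function(x) x@origin)
#' @describeIn gridOrigin origin of a grid definition.
#' @export
setMethod("gridOrigin", "GridDefinition", function(x) x@origin)

#' @describeIn classCodes codes with labels on the raster.
#' @export
setMethod("classCodes", "LandCoverRaster",
    function(x) names(x@classLabels))
#' @describeIn classCodes column codes of the area table.
#' @export
setMethod("classCodes", "ClassAreaTable", function(x) colnames(x@areas))

#' @describeIn classLabels label map of the raster.
#' @export
setMethod("classLabels", "LandCoverRaster", function(x) x@classLabels)

#' @describeIn zoneIds ids of a zone set.
#' @export
setMethod("zoneIds", "ZoneSet", function(x) x@ids)
#' @describeIn zoneIds row ids of an area table.
#' @export
setMethod("zoneIds", "ClassAreaTable", function(x) rownames(x@areas))

#' @describeIn zonePopulation populations of a zone set.
#' @export
setMethod("zonePopulation", "ZoneSet", function(x) {
    stats::setNames(x@population, x@ids)
})

#' @describeIn zoneCentroids centroids of a zone set.
#' @export
setMethod("zoneCentroids", "ZoneSet", function(x) {
    m <- x@centroids
    rownames(m) <- x@ids
    m
})

#' @describeIn classAreas the area matrix.
#' @export
setMethod("classAreas", "ClassAreaTable", function(x) x@areas)

#' @describeIn gridValues persons per cell.
#' @export
setMethod("gridValues", "PopulationGrid", function(x) x@values)
#' @describeIn gridValues per-cell covered flags.
#' @export
setMethod("gridValues", "CoverageGrid", function(x) x@covered)

#' @describeIn densityPerKm2 density view of a population grid.
#' @export
setMethod("densityPerKm2", "PopulationGrid", function(x) {
    x@values / (x@grid@cellSize^2 / 1e6)
})

#' Number of zones
#' @param x a \linkS4class{ZoneSet}.
#' @return integer(1).
#' @export
nZones <- function(x) length(x@ids)

# ---- show methods -----------------------------------------------------------

setMethod("show", "GridDefinition", function(object) {
    cat(sprintf("GridDefinition: %d x %d cells of %g m, origin (%g, %g)\n",
                object@nrow, object@ncol, object@cellSize,
                object@origin[1], object@origin[2]))
})

setMethod("show", "LandCoverRaster", function(object) {
    cat(sprintf("LandCoverRaster: %d x %d cells of %g m (%.2f km^2)\n",
                nrow(object@codes), ncol(object@codes), object@cellSize,
                length(object@codes) * object@cellSize^2 / 1e6))
    tab <- table(factor(as.vector(object@codes),
                        levels = names(object@classLabels)))
    shares <- round(100 * tab / sum(tab), 1)
    cat("  classes: ",
        paste0(object@classLabels, " (", shares, "%)", collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "ZoneSet", function(object) {
    cat(sprintf("ZoneSet: %d zones, total population %.0f\n",
                length(object@ids), sum(object@population)))
})

setMethod("show", "ClassAreaTable", function(object) {
    cat(sprintf("ClassAreaTable: %d zones x %d classes, total %.3f km^2\n",
                nrow(object@areas), ncol(object@areas),
                sum(object@areas) / 1e6))
    if (length(object@emptyZones))
        cat("  empty zones:", paste(object@emptyZones, collapse = ", "), "\n")
})

setMethod("show", "GridCellAreas", function(object) {
    cat(sprintf("GridCellAreas: %d (zone, class, cell) entries on a %d x %d grid of %g m\n",
                nrow(object@table), object@grid@nrow, object@grid@ncol,
                object@grid@cellSize))
})

setMethod("show", "CoefficientField", function(object) {
    cat(sprintf("CoefficientField (%s): %d zones x %d classes%s\n",
                object@provenance, nrow(object@initial),
                ncol(object@initial),
                if (nrow(object@adjusted)) ", rescaled" else ""))
})

setMethod("show", "PopulationGrid", function(object) {
    tot <- sum(object@values)
    cat(sprintf("PopulationGrid: %d x %d cells of %g m, total %.1f persons, peak %.1f/cell\n",
                object@grid@nrow, object@grid@ncol, object@grid@cellSize,
                tot, max(object@values)))
})

setMethod("show", "TravelNetwork", function(object) {
    cat(sprintf("TravelNetwork: %d nodes (%d intersections), %d edges, %d park entrances\n",
                nrow(object@coords), sum(object@intersection),
                igraph::ecount(object@graph), length(object@sources)))
    cat(sprintf("  speed %g m/s, intersection delay %g min\n",
                object@speed, object@penalty))
})

setMethod("show", "ServiceArea", function(object) {
    cat(sprintf("ServiceArea: %d/%d nodes within %g min\n",
                sum(object@covered), length(object@times), object@threshold))
})

setMethod("show", "CoverageGrid", function(object) {
    cat(sprintf("CoverageGrid: %d/%d cells covered at %g min\n",
                sum(object@covered), length(object@covered),
                object@threshold))
})

setMethod("show", "OLSFit", function(object) {
    cat(sprintf("OLSFit (%s): R2 %.3f, adj R2 %.3f, AIC %.3f\n",
                if (object@noIntercept) "no intercept" else "with intercept",
                object@r2, object@adjR2, object@aic))
    print(round(object@coefficients, 6))
})

setMethod("show", "GWRFit", function(object) {
    cat(sprintf("GWRFit: %s kernel, bandwidth %d neighbours, tr(S) %.2f\n",
                object@kernel, object@bandwidth, object@trS))
    cat(sprintf("  R2 %.3f, adj R2 %.3f, AICc %.3f\n",
                object@r2, object@adjR2, object@aicc))
})

setMethod("show", "MoranResult", function(object) {
    cat(sprintf("Moran's I = %.4f (expected %.4f), z = %.2f, p = %.3f [%s]\n",
                object@I, object@expected, object@z, object@p,
                object@scheme))
})

setMethod("show", "ModelComparison", function(object) {
    cat(sprintf("Model comparison: delta AIC (OLS - GWR) = %.3f -> %s\n",
                object@deltaAIC, object@preferred))
    cat(sprintf("  adj R2: OLS %.3f, GWR %.3f\n",
                object@olsAdjR2, object@gwrAdjR2))
    cat(sprintf("  residual Moran's I: OLS %.4f (p %.3f), GWR %.4f (p %.3f)\n",
                object@olsMoran@I, object@olsMoran@p,
                object@gwrMoran@I, object@gwrMoran@p))
})

setMethod("show", "AccuracyReport", function(object) {
    cat(sprintf("AccuracyReport: overall accuracy %.4f%%, kappa %.4f\n",
                100 * object@overallAccuracy, object@kappa))
})

setMethod("show", "ErrorReport", function(object) {
    cat(sprintf("ErrorReport: mean |relative error| %.1f%% over %d zones\n",
                object@meanAbs, length(object@errors)))
    cat(sprintf("  |E| bins: <=10%%: %d, 10-20%%: %d, 20-30%%: %d, >30%%: %d\n",
                object@bins[1], object@bins[2], object@bins[3],
                object@bins[4]))
})

setMethod("show", "EquityReport", function(object) {
    cat(sprintf("EquityReport: %.1f%% of population covered (%.0f of %.0f persons)\n",
                object@coveredFractionPct, object@coveredPopulation,
                object@coveredPopulation + object@uncoveredPopulation))
    cat(sprintf("  covered area %.3f km^2 (%.1f%% of study area)\n",
                object@coveredAreaKm2, object@areaFractionPct))
    if (nrow(object@streets))
        cat(sprintf("  %d streets, %d fully covered (equitable)\n",
                    nrow(object@streets),
                    sum(object@streets$coverage_pct >= 100 - 1e-9)))
})

setMethod("show", "CityConfig", function(object) {
    cat(sprintf("CityConfig: %d x %d cells of %g m, %d classes, %d x %d blocks, seed %d\n",
                object@rasterWidth, object@rasterHeight, object@cellSize,
                object@nClasses, object@nBlocksX, object@nBlocksY,
                object@seed))
})

setMethod("show", "SyntheticCity", function(object) {
    cat("SyntheticCity\n")
    show(object@landCover)
    show(object@zones)
    cat(sprintf("  %d road segments, %d park entrances\n",
                nrow(object@roads), nrow(object@parkEntrances)))
})
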