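#' @include AllGenerics.R
NULL

#' Pipeline configuration
#'
#' Collects the tunable parameters of the full equity pipeline with the
#' study defaults: a 150 m analysis grid, 1 m/s walking speed, 0.5 min
#' intersection delay and a 15 min accessibility threshold.
#'
#' @param gridSize analysis cell size, metres; must be an integer multiple
#'   of the land-cover cell size.
#' @param speed walking speed, m/s.
#' @param penalty intersection crossing delay, minutes.
#' @param threshold accessibility budget, minutes.
#' @param regression "gwr" or "ols".
#' @param noIntercept fix the regression constant at zero (default TRUE,
#'   the dasymetric constraint).
#' @param predictors class codes to use, or "auto" to keep the classes
#'   whose Spearman rank correlation with population is significant at
#'   0.05 (all classes if none are).
#' @param bandwidth adaptive neighbour count for GWR, or "auto" for AICc
#'   selection.
#' @param moranScheme Moran's I weight scheme ("idw" or "queen").
#' @param clamp clamp negative fitted densities to zero.
#' @param maxOffNetwork maximum off-network approach distance, metres.
#' @param snapTol park-entrance snap tolerance, metres.
#' @param seed RNG seed for permutation tests.
#' @return a list of class "PipelineConfig".
#' @export
pipelineConfig <- function(gridSize = 150, speed = 1, penalty = 0.5,
                           threshold = 15,
                           regression = c("gwr", "ols"),
                           noIntercept = TRUE, predictors = "auto",
                           bandwidth = "auto", moranScheme = "idw",
                           clamp = TRUE, maxOffNetwork = 500,
                           snapTol = 100, seed = 1L) {
    regression <- match.arg(regression)
    stopifnot(gridSize > 0, speed > 0, penalty >= 0, threshold > 0,
              maxOffNetwork > 0)
    structure(list(gridSize = gridSize, speed = speed, penalty = penalty,
                   threshold = threshold, regression = regression,
                   noIntercept = noIntercept, predictors = predictors,
                   bandwidth = bandwidth, moranScheme = moranScheme,
                   clamp = clamp, maxOffNetwork = maxOffNetwork,
                   snapTol = snapTol, seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML document whose keys are the arguments of
#' \code{\link{pipelineConfig}}; absent keys keep their defaults.
#'
#' @param path YAML file.
#' @return a PipelineConfig.
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(pipelineConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    do.call(pipelineConfig, vals)
}

#' @export
print.PipelineConfig <- function(x, ...) {
    cat("PipelineConfig\n")
    for (k in names(x)) cat(sprintf("  %s: %s\n", k,
                                    paste(format(x[[k]]), collapse = " ")))
    invisible(x)
}

.stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
    message(sprintf("[%s] done in %.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    out
}

#' Run the full park green-space equity pipeline
#'
#' Sequences the whole analysis: zonal class areas, predictor screening,
#' global (OLS) and local (GWR) population models with comparison
#' diagnostics, coefficient rescaling to block totals, grid inversion of
#' population, walking-time service area of park entrances, per-cell
#' coverage, and the equity overlay with street-scale statistics.
#' Deterministic for a fixed configuration and inputs.
#'
#' @param landCover a \linkS4class{LandCoverRaster}.
#' @param zones a \linkS4class{ZoneSet} of census blocks.
#' @param roads data.frame of road segments (x0, y0, x1, y1).
#' @param parkEntrances two-column coordinate matrix.
#' @param config a \code{\link{pipelineConfig}}.
#' @param streets optional \linkS4class{ZoneSet} of streets for the
#'   street-scale statistics (defaults to the blocks).
#' @param outDir optional directory; when given, the intermediate tables,
#'   grids and a run manifest are written there.
#' @return list with components: areas, screen, ols, gwr (NULL in OLS
#'   mode), comparison, field, errors, cellAreas, popGrid, network,
#'   service, coverage, report (\linkS4class{EquityReport}), config.
#' @examples
#' city <- generateCity(cityConfig(nBlocksX = 4, nBlocksY = 4,
#'                                 rasterWidth = 60, rasterHeight = 60,
#'                                 cellSize = 50, nParks = 3))
#' res <- runPipeline(city@landCover, city@zones, city@roads,
#'                    city@parkEntrances,
#'                    config = pipelineConfig(gridSize = 250,
#'                                            regression = "ols"))
#' res$report
#' @export
runPipeline <- function(landCover, zones, roads, parkEntrances,
                        config = pipelineConfig(), streets = NULL,
                        outDir = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    # fail fast on grid incompatibility before any computation
    .gridDefinition(landCover, config$gridSize)
    set.seed(config$seed)
    areas <- .stage("zonal class areas",
                    zonalClassAreas(landCover, zones))
    screen <- .stage("spearman screen", spearmanScreen(areas, zones))
    predictors <- config$predictors
    if (identical(predictors, "auto")) {
        predictors <- screen$class[!is.na(screen$sig05) & screen$sig05]
        if (!length(predictors)) predictors <- classCodes(areas)
    }
    ols <- .stage("ols fit",
                  fitOLS(areas, zones, predictors, config$noIntercept))
    gwr <- NULL
    comparison <- NULL
    if (config$regression == "gwr") {
        bw <- config$bandwidth
        if (identical(bw, "auto"))
            bw <- .stage("bandwidth selection",
                         selectBandwidth(areas, zones, predictors,
                                         noIntercept = config$noIntercept))
        gwr <- .stage("gwr fit",
                      fitGWR(areas, zones, predictors, bw,
                             noIntercept = config$noIntercept))
        comparison <- .stage("model comparison",
                             compareModels(ols, gwr, zones,
                                           scheme = config$moranScheme))
    }
    fit <- if (config$regression == "gwr") gwr else ols
    field <- coefficientField(fit, zones, clamp = config$clamp)
    pHat <- predictBlockPopulation(field, areas)
    errors <- .stage("error report",
                     errorReport(zones@population, pHat, ids = zoneIds(zones)))
    field <- .stage("coefficient rescaling",
                    rescaleCoefficients(field, areas, zones@population, pHat))
    cellAreas <- .stage("grid class areas",
                        gridClassAreas(landCover, zones, config$gridSize))
    popGrid <- .stage("grid population", gridPopulation(field, cellAreas))
    network <- .stage("network build",
                      buildNetwork(roads, config$speed, config$penalty))
    network <- .stage("entrance snapping",
                      snapEntrances(network, parkEntrances, config$snapTol))
    service <- .stage("service area", serviceArea(network, config$threshold))
    coverage <- .stage("grid coverage",
                       gridCoverage(service, network, popGrid@grid,
                                    config$maxOffNetwork))
    if (is.null(streets)) streets <- zones
    report <- .stage("equity overlay",
                     overlayCoverage(popGrid, coverage, streets))
    out <- list(areas = areas, screen = screen, ols = ols, gwr = gwr,
                comparison = comparison, field = field, errors = errors,
                cellAreas = cellAreas, popGrid = popGrid, network = network,
                service = service, coverage = coverage, report = report,
                config = config)
    if (!is.null(outDir)) .writePipelineOutputs(out, zones, outDir)
    out
}

.writePipelineOutputs <- function(res, zones, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    A <- classAreas(res$areas)
    long <- data.frame(zone_id = rep(rownames(A), times = ncol(A)),
                       class_code = rep(colnames(A), each = nrow(A)),
                       area_m2 = as.vector(A))
    utils::write.csv(long, file.path(outDir, "class_areas.csv"),
                     row.names = FALSE)
    utils::write.csv(stats::setNames(res$cellAreas@table,
                                     c("zone_id", "class_code", "cell_id",
                                       "area_m2")),
                     file.path(outDir, "grid_class_areas.csv"),
                     row.names = FALSE)
    adj <- res$field@adjusted
    utils::write.csv(data.frame(zone_id = rep(rownames(adj), ncol(adj)),
                                class_code = rep(colnames(adj),
                                                 each = nrow(adj)),
                                coefficient = as.vector(adj)),
                     file.path(outDir, "coefficients_adjusted.csv"),
                     row.names = FALSE)
    g <- res$popGrid
    writeAsciiGrid(g@values, g@grid@cellSize, g@grid@origin,
                   file.path(outDir, "population_per_cell.asc"))
    writeAsciiGrid(densityPerKm2(g), g@grid@cellSize, g@grid@origin,
                   file.path(outDir, "population_per_km2.asc"))
    cov <- res$coverage
    writeAsciiGrid(cov@covered + 0, cov@grid@cellSize, cov@grid@origin,
                   file.path(outDir, "coverage_mask.asc"))
    la <- res$report@lowAccess
    writeAsciiGrid(la@values, la@grid@cellSize, la@grid@origin,
                   file.path(outDir, "low_access_population.asc"))
    utils::write.csv(res$report@streets,
                     file.path(outDir, "street_equity.csv"),
                     row.names = FALSE)
    summary <- list(
        covered_population = res$report@coveredPopulation,
        uncovered_population = res$report@uncoveredPopulation,
        covered_population_pct = res$report@coveredFractionPct,
        covered_area_km2 = res$report@coveredAreaKm2,
        covered_area_pct = res$report@areaFractionPct,
        mean_abs_relative_error_pct = res$errors@meanAbs)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(config = unclass(res$config),
                     package = "parkEquity",
                     version = as.character(utils::packageVersion("parkEquity")),
                     grid = list(cellSize = g@grid@cellSize,
                                 nrow = g@grid@nrow, ncol = g@grid@ncol,
                                 origin = g@grid@origin))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(outDir)
}
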