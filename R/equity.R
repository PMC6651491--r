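#' @include AllGenerics.R
NULL

.sameGrid <- function(a, b) {
    isTRUE(all.equal(a@cellSize, b@cellSize)) &&
        isTRUE(all.equal(a@origin, b@origin)) &&
        a@nrow == b@nrow && a@ncol == b@ncol
}

#' Overlay population and accessibility coverage
#'
#' Masks the dasymetric population grid with the walking-time coverage to
#' produce the low-accessibility population surface and the headline
#' totals: covered and uncovered population (persons), the covered
#' fraction of total population (%), and the covered study area (km^2 and
#' % of study area). When street zones are supplied, per-street statistics
#' with equity classes are attached (see \code{\link{streetEquity}}).
#'
#' @param pop a \linkS4class{PopulationGrid}.
#' @param coverage a \linkS4class{CoverageGrid} on the identical grid.
#' @param streets optional \linkS4class{ZoneSet} of streets.
#' @param thresholds optional equity-class thresholds, see
#'   \code{\link{classifyEquity}}.
#' @return an \linkS4class{EquityReport}.
#' @export
overlayCoverage <- function(pop, coverage, streets = NULL,
                            thresholds = NULL) {
    stopifnot(is(pop, "PopulationGrid"), is(coverage, "CoverageGrid"))
    if (!.sameGrid(pop@grid, coverage@grid))
        stop("population and coverage grids differ")
    cov <- coverage@covered
    vals <- pop@values
    low <- vals * !cov
    coveredPop <- sum(vals[cov])
    uncoveredPop <- sum(low)
    total <- coveredPop + uncoveredPop
    mask <- pop@studyMask
    cellKm2 <- pop@grid@cellSize^2 / 1e6
    coveredArea <- sum(cov & mask) * cellKm2
    areaPct <- 100 * sum(cov & mask) / max(1, sum(mask))
    lowGrid <- new("PopulationGrid", values = low, grid = pop@grid,
                   studyMask = mask)
    streetsDf <- data.frame()
    if (!is.null(streets))
        streetsDf <- streetEquity(pop, coverage, streets, thresholds)
    new("EquityReport", lowAccess = lowGrid,
        coveredPopulation = coveredPop, uncoveredPopulation = uncoveredPop,
        coveredFractionPct = if (total > 0) 100 * coveredPop / total else 100,
        coveredAreaKm2 = coveredArea, areaFractionPct = areaPct,
        streets = streetsDf)
}

# assign analysis cells to streets by cell centre, consistent with the
# raster-to-zone convention
.cellStreetMap <- function(grid, streets) {
    cs <- grid@cellSize
    cx <- grid@origin[1] + (seq_len(grid@ncol) - 0.5) * cs
    cy <- grid@origin[2] - (seq_len(grid@nrow) - 0.5) * cs
    centres <- cbind(rep(cx, each = grid@nrow), rep(cy, times = grid@ncol))
    assign <- rep(NA_integer_, nrow(centres))
    for (si in seq_along(streets@ids)) {
        poly <- streets@polygons[[si]]
        bb <- apply(poly, 2, range)
        cand <- which(is.na(assign) &
                      centres[, 1] >= bb[1, 1] & centres[, 1] <= bb[2, 1] &
                      centres[, 2] >= bb[1, 2] & centres[, 2] <= bb[2, 2])
        if (!length(cand)) next
        inside <- mgcv::in.out(poly, centres[cand, , drop = FALSE])
        assign[cand[inside]] <- si
    }
    assign
}

#' Street-scale equity statistics
#'
#' Sums total and low-accessibility population per street (cell-centre
#' zonal sums over the analysis grid) and reports per-street coverage.
#' Streets fully covered (100\%) are the equitable class; the rest are
#' binned by their uncovered population via \code{\link{classifyEquity}}.
#'
#' @param pop a \linkS4class{PopulationGrid}.
#' @param coverage the matching \linkS4class{CoverageGrid}.
#' @param streets a \linkS4class{ZoneSet} of street polygons covering the
#'   grid extent.
#' @param thresholds optional explicit class thresholds.
#' @return data.frame: street_id, population, uncovered, coverage_pct,
#'   class.
#' @export
streetEquity <- function(pop, coverage, streets, thresholds = NULL) {
    stopifnot(is(pop, "PopulationGrid"), is(coverage, "CoverageGrid"),
              is(streets, "ZoneSet"))
    if (!.sameGrid(pop@grid, coverage@grid))
        stop("population and coverage grids differ")
    smap <- .cellStreetMap(pop@grid, streets)
    vals <- as.vector(pop@values)
    low <- as.vector(pop@values * !coverage@covered)
    lost <- is.na(smap) & vals > 0
    if (any(lost))
        warning(sprintf("%.1f persons fall outside every street polygon",
                        sum(vals[lost])))
    n <- length(streets@ids)
    tot <- unname(tapply(vals, factor(smap, levels = seq_len(n)), sum))
    unc <- unname(tapply(low, factor(smap, levels = seq_len(n)), sum))
    tot[is.na(tot)] <- 0; unc[is.na(unc)] <- 0
    zeroCell <- tabulate(smap[!is.na(smap)], nbins = n) == 0
    if (any(zeroCell))
        warning("streets containing no analysis cell: ",
                paste(streets@ids[zeroCell], collapse = ", "))
    coverPct <- ifelse(tot > 0, 100 * (1 - unc / tot), 100)
    data.frame(street_id = streets@ids, population = tot, uncovered = unc,
               coverage_pct = coverPct,
               class = classifyEquity(unc, thresholds),
               stringsAsFactors = FALSE)
}

#' Classify streets by uncovered population
#'
#' Streets with zero uncovered population are "equitable". The remainder
#' are binned by uncovered count: by default at the quartiles of the
#' nonzero uncovered counts, or at explicit strictly increasing
#' thresholds.
#'
#' @param uncovered numeric, uncovered persons per street.
#' @param thresholds optional strictly increasing bin edges; default the
#'   quartiles of the nonzero counts.
#' @return character vector of class labels.
#' @examples
#' classifyEquity(c(0, 5, 500, 5e4, 2e5), thresholds = c(1e4, 1e5))
#' @export
classifyEquity <- function(uncovered, thresholds = NULL) {
    if (any(uncovered < 0)) stop("uncovered counts must be non-negative")
    nz <- uncovered[uncovered > 0]
    if (is.null(thresholds)) {
        if (!length(nz))
            return(rep("equitable", length(uncovered)))
        thresholds <- unique(stats::quantile(nz, c(0.25, 0.5, 0.75),
                                             names = FALSE))
    }
    if (length(thresholds) > 1 && any(diff(thresholds) <= 0))
        stop("thresholds must be strictly increasing")
    labels <- c("slightly unequal", "unequal", "very unequal",
                "extremely unequal")
    nb <- length(thresholds) + 1
    labels <- if (nb <= length(labels))
        labels[seq(length(labels) - nb + 1, length(labels))]
    else paste0("unequal_", seq_len(nb))
    bin <- findInterval(uncovered, thresholds, left.open = TRUE) + 1
    out <- labels[bin]
    out[uncovered == 0] <- "equitable"
    out
}
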