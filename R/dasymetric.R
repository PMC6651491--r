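#' @include AllGenerics.R
NULL

#' Build a coefficient field from a fitted model
#'
#' Turns a global or local regression into the per-zone, per-class density
#' field of the dasymetric model: OLS coefficients are replicated across
#' zones; GWR local coefficients are taken at each zone's centroid and
#' applied uniformly within the zone. Negative fitted densities violate
#' "no land without population" and are clamped to zero by default (they
#' would also break the block-total rescaling).
#'
#' @param fit an \linkS4class{OLSFit} or \linkS4class{GWRFit} with no
#'   intercept (an intercept has no per-class area to spread over).
#' @param zones the \linkS4class{ZoneSet} the model was fitted on.
#' @param clamp clamp negative coefficients to 0 (default TRUE).
#' @return a \linkS4class{CoefficientField} (initial only; rescale with
#'   \code{\link{rescaleCoefficients}}).
#' @export
coefficientField <- function(fit, zones, clamp = TRUE) {
    if (is(fit, "OLSFit")) {
        if (!fit@noIntercept && abs(fit@intercept) > 1e-9)
            stop("dasymetric use requires a no-intercept fit")
        init <- matrix(rep(fit@coefficients, each = nZones(zones)),
                       nZones(zones), length(fit@coefficients),
                       dimnames = list(zoneIds(zones), fit@predictors))
        prov <- "ols"
    } else if (is(fit, "GWRFit")) {
        if (!fit@noIntercept)
            stop("dasymetric use requires a no-intercept fit")
        init <- fit@local[, fit@predictors, drop = FALSE]
        prov <- "gwr"
    } else stop("fit must be an OLSFit or GWRFit")
    if (clamp) init[init < 0] <- 0
    new("CoefficientField", initial = init, provenance = prov)
}

.fieldMatrix <- function(coeffs, which) {
    m <- slot(coeffs, which)
    if (!nrow(m)) stop("coefficient field has no '", which, "' matrix; ",
                       "run rescaleCoefficients() first")
    m
}

#' Predict block populations from a coefficient field
#'
#' p'_i = sum_j coef(i, j) * S_ij: the dasymetric forward prediction of
#' each zone's population from its class areas.
#'
#' @param coeffs a \linkS4class{CoefficientField}.
#' @param areas a \linkS4class{ClassAreaTable} over at least the field's
#'   classes.
#' @param which "initial" (default) or "adjusted" coefficients.
#' @return named numeric of predicted persons per zone.
#' @export
predictBlockPopulation <- function(coeffs, areas, which = "initial") {
    cf <- .fieldMatrix(coeffs, which)
    A <- classAreas(areas)
    missing <- setdiff(colnames(cf), colnames(A))
    if (length(missing))
        stop("area table lacks class columns: ",
             paste(missing, collapse = ", "))
    if (!identical(rownames(cf), rownames(A)))
        stop("coefficient field and area table refer to different zones")
    rowSums(cf * A[, colnames(cf), drop = FALSE])
}

#' Signed relative prediction error
#'
#' E_i = (p'_i - p_i) / p_i * 100 (%). Zones with zero census population
#' have no defined relative error and return NA with a warning.
#'
#' @param p observed persons per zone.
#' @param pHat predicted persons per zone.
#' @return numeric, percent.
#' @examples
#' relativeError(100, 120)            # +20
#' relativeError(576000, 588000)      # +2.083...
#' @export
relativeError <- function(p, pHat) {
    if (length(p) != length(pHat)) stop("length mismatch")
    out <- rep(NA_real_, length(p))
    bad <- p == 0
    if (any(bad)) warning(sum(bad), " zone(s) with zero population: ",
                          "relative error undefined there")
    out[!bad] <- (pHat[!bad] - p[!bad]) / p[!bad] * 100
    out
}

#' Rescale coefficients to restore block totals
#'
#' The mass-preserving correction a'_ij = (p_i / p'_i) * a_ij: after
#' rescaling, re-predicting every zone returns its census count exactly,
#' so the subsequent grid inversion conserves total population
#' (pycnophylactic property). Rescaling is idempotent. Zones predicted at
#' zero but with positive census population fall back to a uniform density
#' over the zone's area outside any excluded classes (logged via message).
#'
#' @param coeffs a \linkS4class{CoefficientField} with initial values.
#' @param areas the \linkS4class{ClassAreaTable} (needed for the fallback).
#' @param p observed persons per zone (in zone order of the field).
#' @param pHat predicted persons per zone; computed from the field if NULL.
#' @param excludeClasses class codes excluded from the uniform fallback
#'   (e.g. the water class), default none.
#' @return the field with the adjusted matrix filled in.
#' @export
rescaleCoefficients <- function(coeffs, areas, p, pHat = NULL,
                                excludeClasses = character(0)) {
    init <- coeffs@initial
    if (length(p) != nrow(init)) stop("p must have one entry per zone")
    if (is.null(pHat)) pHat <- predictBlockPopulation(coeffs, areas)
    if (length(pHat) != nrow(init)) stop("pHat must have one entry per zone")
    adj <- init
    ok <- pHat > 0
    adj[ok, ] <- (p[ok] / pHat[ok]) * init[ok, , drop = FALSE]
    fall <- !ok & p > 0
    if (any(fall)) {
        message(sum(fall), " zone(s) predicted at zero with positive census ",
                "population; distributing uniformly over non-excluded area")
        A <- classAreas(areas)[rownames(init), colnames(init), drop = FALSE]
        keep <- setdiff(colnames(init), as.character(excludeClasses))
        for (i in which(fall)) {
            tot <- sum(A[i, keep])
            if (tot <= 0)
                stop("zone ", rownames(init)[i],
                     " has positive population but no distributable area")
            adj[i, ] <- 0
            adj[i, keep] <- p[i] / tot
        }
    }
    zero <- !ok & p == 0
    adj[zero, ] <- 0
    out <- coeffs
    out@adjusted <- adj
    out
}

#' Invert population onto the analysis grid
#'
#' pop_k = sum_i sum_j a'_ij * s_ijk: each analysis cell accumulates the
#' contributions of every (zone, class) share it contains, so cells
#' straddling zone boundaries sum their block parts additively. After
#' rescaling, the grid total equals the census total.
#'
#' @param coeffs a rescaled \linkS4class{CoefficientField} (uses the
#'   adjusted matrix; falls back to initial with a warning if absent).
#' @param cellAreas a \linkS4class{GridCellAreas}.
#' @return a \linkS4class{PopulationGrid}.
#' @export
gridPopulation <- function(coeffs, cellAreas) {
    stopifnot(is(cellAreas, "GridCellAreas"))
    which <- if (nrow(coeffs@adjusted)) "adjusted" else {
        warning("coefficient field not rescaled; using initial coefficients")
        "initial"
    }
    cf <- slot(coeffs, which)
    tab <- cellAreas@table
    zi <- match(tab$zone, rownames(cf))
    if (anyNA(zi))
        stop("cell areas reference unknown zones: ",
             paste(unique(tab$zone[is.na(zi)]), collapse = ", "))
    ci <- match(as.character(tab$class), colnames(cf))
    contrib <- ifelse(is.na(ci), 0, cf[cbind(zi, ifelse(is.na(ci), 1L, ci))]) *
        tab$area
    grid <- cellAreas@grid
    vals <- matrix(0, grid@nrow, grid@ncol)
    agg <- rowsum(contrib, tab$cell)
    cells <- as.integer(rownames(agg))
    # cell index is row-major; matrix storage is column-major
    rr <- (cells - 1L) %/% grid@ncol + 1L
    cc <- (cells - 1L) %% grid@ncol + 1L
    vals[cbind(rr, cc)] <- agg
    mask <- matrix(FALSE, grid@nrow, grid@ncol)
    allCells <- unique(tab$cell)
    mask[cbind((allCells - 1L) %/% grid@ncol + 1L,
               (allCells - 1L) %% grid@ncol + 1L)] <- TRUE
    new("PopulationGrid", values = vals, grid = grid, studyMask = mask)
}

#' Relative-error report of the dasymetric prediction
#'
#' Bins the absolute per-zone relative errors into the standard brackets
#' (<= 10, 10-20, 20-30, > 30 percent) and reports the mean absolute
#' relative error; zones with zero census population are excluded from
#' both with a warning.
#'
#' @param p observed persons per zone (named or in zone order).
#' @param pHat predicted persons per zone.
#' @param ids optional zone ids for the undefined list.
#' @return an \linkS4class{ErrorReport}.
#' @examples
#' errorReport(c(100, 100, 100, 100), c(105, 115, 125, 150))
#' @export
errorReport <- function(p, pHat, ids = NULL) {
    if (!length(p)) stop("need at least one zone")
    if (is.null(ids)) ids <- names(p)
    if (is.null(ids)) ids <- as.character(seq_along(p))
    e <- relativeError(p, pHat)
    ae <- abs(e)
    def <- !is.na(ae)
    bins <- c(sum(ae[def] <= 10),
              sum(ae[def] > 10 & ae[def] <= 20),
              sum(ae[def] > 20 & ae[def] <= 30),
              sum(ae[def] > 30))
    new("ErrorReport", errors = e, bins = as.integer(bins),
        meanAbs = mean(ae[def]), undefined = ids[!def])
}
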