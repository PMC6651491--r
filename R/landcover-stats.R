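#' @include AllGenerics.R
NULL

# centre coordinates of every raster cell, row-major matrix order preserved
.cellCentres <- function(raster) {
    cs <- raster@cellSize
    nr <- nrow(raster@codes); nc <- ncol(raster@codes)
    x <- raster@origin[1] + (seq_len(nc) - 0.5) * cs
    y <- raster@origin[2] - (seq_len(nr) - 0.5) * cs
    cbind(x = rep(x, each = nr), y = rep(y, times = nc))
}

# assign each raster cell to the first zone whose polygon contains its
# centre; cells outside every zone get NA. Returns an integer matrix the
# shape of the raster. Cell-centre assignment (not polygon clipping) keeps
# area sums exactly conserved.
.cellZoneMap <- function(raster, zones) {
    centres <- .cellCentres(raster)
    nr <- nrow(raster@codes)
    assign <- rep(NA_integer_, nrow(centres))
    for (zi in seq_along(zones@ids)) {
        poly <- zones@polygons[[zi]]
        bb <- apply(poly, 2, range)
        cand <- which(is.na(assign) &
                      centres[, 1] >= bb[1, 1] & centres[, 1] <= bb[2, 1] &
                      centres[, 2] >= bb[1, 2] & centres[, 2] <= bb[2, 2])
        if (!length(cand)) next
        inside <- mgcv::in.out(poly, centres[cand, , drop = FALSE])
        assign[cand[inside]] <- zi
    }
    matrix(assign, nrow = nr)
}

#' Per-zone land-cover class areas
#'
#' Counts the area of each land-cover class inside each zone (the S_ij of
#' the dasymetric model). Each raster cell is assigned to exactly one zone
#' by its centre point; per-class area is the cell count times cellSize^2.
#' Nodata cells are excluded from all sums. Zones containing no cell centre
#' are flagged and get a zero row.
#'
#' @param raster a \linkS4class{LandCoverRaster}.
#' @param zones a \linkS4class{ZoneSet} sharing the raster's coordinate
#'   frame.
#' @return a \linkS4class{ClassAreaTable}.
#' @examples
#' city <- generateCity(cityConfig(nBlocksX = 2, nBlocksY = 2,
#'                                 rasterWidth = 20, rasterHeight = 20))
#' zonalClassAreas(city@landCover, city@zones)
#' @export
zonalClassAreas <- function(raster, zones) {
    stopifnot(is(raster, "LandCoverRaster"), is(zones, "ZoneSet"))
    zmap <- .cellZoneMap(raster, zones)
    codes <- raster@codes
    keep <- !is.na(zmap) & codes != raster@nodataCode
    classChr <- classCodes(raster)
    tab <- table(factor(zmap[keep], levels = seq_along(zones@ids)),
                 factor(codes[keep], levels = as.integer(classChr)))
    areas <- unclass(tab) * raster@cellSize^2
    dimnames(areas) <- list(zones@ids, classChr)
    empty <- zones@ids[rowSums(areas) == 0 &
                       tabulate(zmap[!is.na(zmap)],
                                nbins = length(zones@ids)) == 0]
    if (length(empty))
        warning("zones containing no raster cell centre: ",
                paste(empty, collapse = ", "))
    new("ClassAreaTable", areas = areas, emptyZones = empty)
}

# analysis-grid definition anchored to the raster origin
.gridDefinition <- function(raster, gridSize) {
    cs <- raster@cellSize
    if (abs(gridSize / cs - round(gridSize / cs)) > 1e-9)
        stop("gridSize must be an integer multiple of the raster cell size; ",
             "resample the raster first")
    new("GridDefinition", cellSize = gridSize, origin = raster@origin,
        nrow = as.integer(ceiling(nrow(raster@codes) * cs / gridSize)),
        ncol = as.integer(ceiling(ncol(raster@codes) * cs / gridSize)))
}

#' Class areas split by analysis-grid cell
#'
#' Splits each zone's class areas across the cells of a coarser analysis
#' grid (the s_ijk of the grid inversion). The grid is anchored to the
#' raster origin and its cell size must be an integer multiple of the
#' raster cell size, so every raster cell maps to exactly one
#' (zone, analysis-cell) pair and the split conserves the per-zone class
#' areas exactly: sum_k s_ijk = S_ij.
#'
#' @param raster a \linkS4class{LandCoverRaster}.
#' @param zones a \linkS4class{ZoneSet}.
#' @param gridSize analysis cell size in metres (default 150).
#' @return a \linkS4class{GridCellAreas}.
#' @examples
#' city <- generateCity(cityConfig(nBlocksX = 2, nBlocksY = 2,
#'                                 rasterWidth = 20, rasterHeight = 20))
#' gca <- gridClassAreas(city@landCover, city@zones, gridSize = 150)
#' @export
gridClassAreas <- function(raster, zones, gridSize = 150) {
    stopifnot(is(raster, "LandCoverRaster"), is(zones, "ZoneSet"))
    grid <- .gridDefinition(raster, gridSize)
    ratio <- as.integer(round(gridSize / raster@cellSize))
    zmap <- .cellZoneMap(raster, zones)
    codes <- raster@codes
    nr <- nrow(codes)
    rows <- rep(seq_len(nr), times = ncol(codes))
    cols <- rep(seq_len(ncol(codes)), each = nr)
    keep <- !is.na(zmap) & codes != raster@nodataCode
    gRow <- (rows[keep] - 1L) %/% ratio + 1L
    gCol <- (cols[keep] - 1L) %/% ratio + 1L
    cell <- (gRow - 1L) * grid@ncol + gCol
    zone <- zones@ids[zmap[keep]]
    cls <- codes[keep]
    key <- paste(zone, cls, cell, sep = "\r")
    area <- rowsum(rep(raster@cellSize^2, sum(keep)), key)
    parts <- do.call(rbind, strsplit(rownames(area), "\r", fixed = TRUE))
    tab <- data.frame(zone = parts[, 1],
                      class = as.integer(parts[, 2]),
                      cell = as.integer(parts[, 3]),
                      area = as.numeric(area),
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$zone, tab$class, tab$cell), ]
    rownames(tab) <- NULL
    new("GridCellAreas", table = tab, grid = grid)
}

#' Classification accuracy from paired label sequences
#'
#' Builds the confusion matrix of a predicted classification against a
#' reference and reports overall accuracy (trace / total) and Cohen's
#' kappa, kappa = (p_o - p_e) / (1 - p_e) with chance agreement
#' p_e = sum_c (row_c * col_c) / N^2. In the degenerate case p_e = 1
#' (a single shared label with perfect agreement) kappa is defined as 1.
#'
#' @param reference reference labels.
#' @param predicted predicted labels, same length.
#' @return an \linkS4class{AccuracyReport}.
#' @examples
#' confusionMatrix(c(1, 1, 2, 2), c(1, 2, 2, 2))
#' @export
confusionMatrix <- function(reference, predicted) {
    if (length(reference) != length(predicted) || !length(reference))
        stop("reference and predicted must have equal positive length")
    labels <- sort(unique(c(reference, predicted)))
    cm <- table(factor(reference, levels = labels),
                factor(predicted, levels = labels))
    cm <- unclass(cm)
    n <- sum(cm)
    po <- sum(diag(cm)) / n
    pe <- sum(rowSums(cm) * colSums(cm)) / n^2
    kappa <- if (abs(1 - pe) < 1e-12) {
        if (po >= 1 - 1e-12) 1 else NA_real_
    } else (po - pe) / (1 - pe)
    new("AccuracyReport", confusion = cm, overallAccuracy = po,
        kappa = kappa)
}
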