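#' @include AllGenerics.R
NULL

#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows from the
#' top of the grid down.
#'
#' @param values numeric matrix (row 1 = top).
#' @param cellSize cell size, metres.
#' @param origin (x, y) of the top-left outer corner.
#' @param path output file.
#' @param nodata value written for NA cells (default -9999).
#' @return invisibly, the path.
#' @export
writeAsciiGrid <- function(values, cellSize, origin, path, nodata = -9999) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("ncols %d", ncol(values)),
                 sprintf("nrows %d", nrow(values)),
                 sprintf("xllcorner %.10g", origin[1]),
                 sprintf("yllcorner %.10g", origin[2] - nrow(values) * cellSize),
                 sprintf("cellsize %.10g", cellSize),
                 sprintf("NODATA_value %.10g", nodata)), con)
    v <- values
    v[is.na(v)] <- nodata
    utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path input file.
#' @return list with values (matrix, NODATA as NA), cellSize, origin
#'   (top-left corner).
#' @export
readAsciiGrid <- function(path) {
    hdr <- readLines(path, n = 6)
    kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
    h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
    vals <- as.matrix(utils::read.table(path, skip = 6))
    dimnames(vals) <- NULL
    vals[vals == h["nodata_value"]] <- NA
    list(values = vals, cellSize = unname(h["cellsize"]),
         origin = unname(c(h["xllcorner"],
                           h["yllcorner"] + nrow(vals) * h["cellsize"])))
}

#' Write a land-cover raster (ASCII grid + JSON sidecar)
#'
#' @param raster a \linkS4class{LandCoverRaster}.
#' @param path output .asc path; the class-label sidecar is written next
#'   to it as <path>.json.
#' @return invisibly, the path.
#' @export
writeLandCover <- function(raster, path) {
    writeAsciiGrid(raster@codes, raster@cellSize, raster@origin, path,
                   nodata = raster@nodataCode)
    jsonlite::write_json(list(classLabels = as.list(raster@classLabels),
                              nodataCode = raster@nodataCode),
                         paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' Read a land-cover raster written by \code{\link{writeLandCover}}
#' @param path the .asc path.
#' @return a \linkS4class{LandCoverRaster}.
#' @export
readLandCover <- function(path) {
    g <- readAsciiGrid(path)
    meta <- jsonlite::read_json(paste0(path, ".json"))
    codes <- g$values
    nodata <- as.integer(meta$nodataCode)
    codes[is.na(codes)] <- nodata
    storage.mode(codes) <- "integer"
    new("LandCoverRaster", codes = codes, cellSize = g$cellSize,
        origin = g$origin,
        classLabels = unlist(meta$classLabels), nodataCode = nodata)
}

.featureCollection <- function(features) {
    list(type = "FeatureCollection", features = features)
}

#' Write zones as GeoJSON
#'
#' Polygon features with properties id and population. Coordinates are in
#' the projected metre frame of the analysis (no CRS member is written).
#'
#' @param zones a \linkS4class{ZoneSet}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeZonesGeoJSON <- function(zones, path) {
    feats <- lapply(seq_along(zones@ids), function(i) {
        ring <- zones@polygons[[i]]
        list(type = "Feature",
             properties = list(id = zones@ids[i],
                               population = zones@population[i]),
             geometry = list(type = "Polygon",
                             coordinates = list(lapply(seq_len(nrow(ring)),
                                 function(r) as.numeric(ring[r, ])))))
    })
    jsonlite::write_json(.featureCollection(feats), path,
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read zones from GeoJSON written by \code{\link{writeZonesGeoJSON}}
#' @param path input file.
#' @return a \linkS4class{ZoneSet}.
#' @export
readZonesGeoJSON <- function(path) {
    fc <- jsonlite::read_json(path)
    ids <- character(0); polys <- list(); pops <- numeric(0)
    cents <- NULL
    for (f in fc$features) {
        id <- as.character(f$properties$id)
        ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                      function(p) as.numeric(unlist(p))))
        ids <- c(ids, id)
        polys[[id]] <- ring
        pops <- c(pops, as.numeric(f$properties$population))
        k <- nrow(ring) - 1  # closed ring: drop the repeated vertex
        cents <- rbind(cents, colMeans(ring[seq_len(k), , drop = FALSE]))
    }
    new("ZoneSet", ids = ids, polygons = polys, population = pops,
        centroids = cents)
}

#' Write road segments as GeoJSON LineStrings
#' @param roads data.frame with x0, y0, x1, y1.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRoadsGeoJSON <- function(roads, path) {
    feats <- lapply(seq_len(nrow(roads)), function(i) {
        list(type = "Feature", properties = list(id = i),
             geometry = list(type = "LineString",
                             coordinates = list(
                                 c(roads$x0[i], roads$y0[i]),
                                 c(roads$x1[i], roads$y1[i]))))
    })
    jsonlite::write_json(.featureCollection(feats), path,
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read road segments from GeoJSON LineStrings
#' @param path input file.
#' @return data.frame with x0, y0, x1, y1, length.
#' @export
readRoadsGeoJSON <- function(path) {
    fc <- jsonlite::read_json(path)
    segs <- lapply(fc$features, function(f) {
        cc <- f$geometry$coordinates
        # polyline features contribute one segment per vertex pair
        do.call(rbind, lapply(seq_len(length(cc) - 1), function(i) {
            a <- as.numeric(unlist(cc[[i]])); b <- as.numeric(unlist(cc[[i + 1]]))
            data.frame(x0 = a[1], y0 = a[2], x1 = b[1], y1 = b[2])
        }))
    })
    out <- do.call(rbind, segs)
    out$length <- sqrt((out$x1 - out$x0)^2 + (out$y1 - out$y0)^2)
    out
}

#' Write points as GeoJSON
#' @param points two-column coordinate matrix.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePointsGeoJSON <- function(points, path) {
    points <- rbind(points)
    feats <- lapply(seq_len(nrow(points)), function(i) {
        list(type = "Feature", properties = list(id = i),
             geometry = list(type = "Point",
                             coordinates = as.numeric(points[i, 1:2])))
    })
    jsonlite::write_json(.featureCollection(feats), path,
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read points from GeoJSON
#' @param path input file.
#' @return two-column coordinate matrix.
#' @export
readPointsGeoJSON <- function(path) {
    fc <- jsonlite::read_json(path)
    out <- do.call(rbind, lapply(fc$features, function(f)
        as.numeric(unlist(f$geometry$coordinates))))
    colnames(out) <- c("x", "y")
    out
}

#' Write a synthetic city to a directory
#'
#' Writes land_cover.asc (+ .json sidecar), zones.geojson, roads.geojson,
#' park_entrances.geojson and truth_coefficients.json (the generating
#' ground truth).
#'
#' @param city a \linkS4class{SyntheticCity}.
#' @param dir output directory (created if needed).
#' @return invisibly, dir.
#' @export
writeCity <- function(city, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLandCover(city@landCover, file.path(dir, "land_cover.asc"))
    writeZonesGeoJSON(city@zones, file.path(dir, "zones.geojson"))
    writeRoadsGeoJSON(city@roads, file.path(dir, "roads.geojson"))
    writePointsGeoJSON(city@parkEntrances,
                       file.path(dir, "park_entrances.geojson"))
    tr <- city@truth@initial
    jsonlite::write_json(list(zones = rownames(tr),
                              classes = colnames(tr),
                              coefficients = unclass(as.data.frame(tr))),
                         file.path(dir, "truth_coefficients.json"),
                         digits = NA)
    invisible(dir)
}
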