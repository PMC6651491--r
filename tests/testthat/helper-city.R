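# shared fixtures and independent oracles, all built in code

smallCityConfig <- function(noiseSd = 0, seed = 1L, nClasses = 3L) {
    cityConfig(rasterWidth = 60L, rasterHeight = 60L, cellSize = 30,
               nClasses = nClasses,
               classProportions = rep(1 / nClasses, nClasses),
               patchScale = 8, nBlocksX = 3L, nBlocksY = 3L,
               trueCoefficients = seq(0.002, 0.02,
                                      length.out = nClasses),
               noiseSd = noiseSd, roadSpacing = 300, nParks = 3L,
               seed = seed)
}

# smooth linear-gradient coefficient surfaces; 3 classes and 210 blocks
# keep every local coefficient identifiable from compositional area data
gradientCityConfig <- function(noiseSd = 0, seed = 1L) {
    cityConfig(rasterWidth = 150L, rasterHeight = 140L,
               nBlocksX = 15L, nBlocksY = 14L,
               nClasses = 3L, classProportions = c(0.3, 0.3, 0.4),
               trueCoefficients = list(
                   function(u, v) 0.002 + 0.010 * u / 4500,
                   function(u, v) 0.015 - 0.010 * v / 4200,
                   function(u, v) 0.005 + 0.015 * u / 4500),
               noiseSd = noiseSd, seed = seed)
}

# single-zone rectangular raster built by hand
makeRaster <- function(codes, cellSize = 30, nodata = 0L,
                       labels = NULL) {
    storage.mode(codes) <- "integer"
    if (is.null(labels)) {
        used <- sort(setdiff(unique(as.vector(codes)), nodata))
        labels <- stats::setNames(paste0("class_", used),
                                  as.character(used))
    }
    new("LandCoverRaster", codes = codes, cellSize = cellSize,
        origin = c(0, nrow(codes) * cellSize), classLabels = labels,
        nodataCode = nodata)
}

rectZone <- function(id, x0, y0, x1, y1, population = 0) {
    list(id = id,
         poly = matrix(c(x0, y0, x1, y0, x1, y1, x0, y1, x0, y0),
                       ncol = 2, byrow = TRUE),
         population = population,
         centroid = c((x0 + x1) / 2, (y0 + y1) / 2))
}

makeZones <- function(...) {
    zs <- list(...)
    new("ZoneSet",
        ids = vapply(zs, `[[`, "", "id"),
        polygons = stats::setNames(lapply(zs, `[[`, "poly"),
                                   vapply(zs, `[[`, "", "id")),
        population = vapply(zs, `[[`, 0, "population"),
        centroids = do.call(rbind, lapply(zs, `[[`, "centroid")))
}

# brute-force zonal areas: explicit per-cell loop with ray-cast
# point-in-polygon, independent of the package's assignment path
pointInPoly <- function(px, py, poly) {
    n <- nrow(poly) - 1
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
        xi <- poly[i, 1]; yi <- poly[i, 2]
        xj <- poly[j, 1]; yj <- poly[j, 2]
        if ((yi > py) != (yj > py) &&
            px < (xj - xi) * (py - yi) / (yj - yi) + xi)
            inside <- !inside
        j <- i
    }
    inside
}

bruteZonalAreas <- function(raster, zones) {
    cs <- raster@cellSize
    classes <- names(raster@classLabels)
    out <- matrix(0, length(zones@ids), length(classes),
                  dimnames = list(zones@ids, classes))
    for (r in seq_len(nrow(raster@codes))) {
        for (cc in seq_len(ncol(raster@codes))) {
            code <- raster@codes[r, cc]
            if (code == raster@nodataCode) next
            px <- raster@origin[1] + (cc - 0.5) * cs
            py <- raster@origin[2] - (r - 0.5) * cs
            for (zi in seq_along(zones@ids)) {
                if (pointInPoly(px, py, zones@polygons[[zi]])) {
                    out[zi, as.character(code)] <-
                        out[zi, as.character(code)] + cs^2
                    break
                }
            }
        }
    }
    out
}

# exhaustive simple-path travel times with the interior-intersection delay;
# feasible only on small graphs
brutePathTimes <- function(edges, times, nNodes, isInt, penalty, sources) {
    adj <- vector("list", nNodes)
    for (e in seq_len(nrow(edges))) {
        a <- edges[e, 1]; b <- edges[e, 2]
        adj[[a]] <- rbind(adj[[a]], c(b, times[e]))
        adj[[b]] <- rbind(adj[[b]], c(a, times[e]))
    }
    best <- rep(Inf, nNodes)
    for (s in sources) {
        v <- rep(FALSE, nNodes); v[s] <- TRUE
        best[s] <- min(best[s], 0)
        # charging a node's delay on departure (never at the origin)
        # charges exactly the interior intersections of each path
        walk <- function(node, visited, cost) {
            if (cost < best[node]) best[node] <<- cost
            nb <- adj[[node]]
            if (is.null(nb)) return(invisible())
            for (k in seq_len(nrow(nb))) {
                nxt <- nb[k, 1]
                if (visited[nxt]) next
                step <- nb[k, 2] +
                    if (node != s && isInt[node]) penalty else 0
                v2 <- visited; v2[nxt] <- TRUE
                walk(nxt, v2, cost + step)
            }
        }
        walk(s, v, 0)
    }
    best
}

# explicit weighted least squares at one location
bruteWLS <- function(X, y, w) {
    sw <- sqrt(w)
    qr.coef(qr(X * sw), y * sw)
}
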