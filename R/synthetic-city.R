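#' @include AllGenerics.R
NULL

#' Build a synthetic-city configuration
#'
#' Defaults describe the validation study region used throughout the
#' package: a 4.5 x 4.32 km area on a 30 m land-cover raster with the seven
#' urban cover classes (woodland, farmland, water, road, bare land, factory
#' buildings, other paving), 90 census blocks, a 300 m road lattice with
#' 15\% of segments missing, and 6 park entrances. Density coefficients are
#' plausible per-class residential densities in persons per m^2 (e.g. 0.018
#' for other paving, i.e. 18,000 persons/km^2 of paved residential fabric).
#'
#' @param rasterWidth,rasterHeight raster size in cells.
#' @param cellSize raster cell size, metres.
#' @param nClasses number of land-cover classes.
#' @param classProportions target class shares (sum to 1).
#' @param patchScale characteristic land-cover patch size, cells.
#' @param nBlocksX,nBlocksY blocks along x and y (must divide the raster).
#' @param trueCoefficients numeric vector (constant densities, persons/m^2)
#'   or list of functions f(u, v) for spatially varying densities.
#' @param noiseSd sd of additive block-population noise, persons.
#' @param roadSpacing road-lattice spacing, metres.
#' @param edgeDropFraction fraction of lattice edges removed.
#' @param nParks number of park entrances.
#' @param seed RNG seed.
#' @return a \linkS4class{CityConfig}.
#' @examples
#' cfg <- cityConfig(nBlocksX = 2, nBlocksY = 2, rasterWidth = 40,
#'                   rasterHeight = 40)
#' city <- generateCity(cfg)
#' @export
cityConfig <- function(rasterWidth = 150L, rasterHeight = 144L,
                       cellSize = 30,
                       nClasses = 7L,
                       classProportions = c(0.15, 0.10, 0.10, 0.12,
                                            0.08, 0.10, 0.35),
                       patchScale = 12,
                       nBlocksX = 10L, nBlocksY = 9L,
                       trueCoefficients = c(0.0008, 0.0004, 0, 0.006,
                                            0.001, 0.004, 0.018),
                       noiseSd = 150,
                       roadSpacing = 300,
                       edgeDropFraction = 0.15,
                       nParks = 6L,
                       seed = 1L) {
    if (length(classProportions) != nClasses)
        classProportions <- rep(1 / nClasses, nClasses)
    new("CityConfig",
        rasterWidth = as.integer(rasterWidth),
        rasterHeight = as.integer(rasterHeight),
        cellSize = cellSize, nClasses = as.integer(nClasses),
        classProportions = classProportions, patchScale = patchScale,
        nBlocksX = as.integer(nBlocksX), nBlocksY = as.integer(nBlocksY),
        trueCoefficients = trueCoefficients, noiseSd = noiseSd,
        roadSpacing = roadSpacing, edgeDropFraction = edgeDropFraction,
        nParks = as.integer(nParks), seed = as.integer(seed))
}

# value-noise field: seeded coarse gaussian grids bilinearly interpolated to
# full resolution and summed over octaves; thresholding it at the class
# quantiles yields contiguous patches with realistic spatial autocorrelation
.valueNoise <- function(nr, nc, scale) {
    mr <- ceiling(nr / scale) + 1L
    mc <- ceiling(nc / scale) + 1L
    coarse <- matrix(stats::rnorm(mr * mc), mr, mc)
    fr <- (seq_len(nr) - 0.5) / scale
    fc <- (seq_len(nc) - 0.5) / scale
    i0 <- pmin(floor(fr), mr - 2L); tr <- fr - i0
    j0 <- pmin(floor(fc), mc - 2L); tc <- fc - j0
    a <- coarse[cbind(rep(i0 + 1L, nc), rep(j0 + 1L, each = nr))]
    b <- coarse[cbind(rep(i0 + 2L, nc), rep(j0 + 1L, each = nr))]
    d <- coarse[cbind(rep(i0 + 1L, nc), rep(j0 + 2L, each = nr))]
    e <- coarse[cbind(rep(i0 + 2L, nc), rep(j0 + 2L, each = nr))]
    tr <- rep(tr, nc); tc <- rep(tc, each = nr)
    v <- (1 - tr) * (1 - tc) * a + tr * (1 - tc) * b +
         (1 - tr) * tc * d + tr * tc * e
    matrix(v, nr, nc)
}

.defaultLabels <- c("woodland", "farmland", "water", "road", "bare_land",
                    "factory", "other_paving")

.makeLandCover <- function(config) {
    nr <- config@rasterHeight; nc <- config@rasterWidth
    field <- .valueNoise(nr, nc, config@patchScale) +
        0.5 * .valueNoise(nr, nc, max(2, config@patchScale / 3)) +
        0.25 * .valueNoise(nr, nc, max(1, config@patchScale / 9))
    cuts <- stats::quantile(field,
                            cumsum(config@classProportions)[-config@nClasses])
    codes <- matrix(findInterval(field, cuts) + 1L, nr, nc)
    labels <- if (config@nClasses == 7L) .defaultLabels else
        paste0("class_", seq_len(config@nClasses))
    names(labels) <- as.character(seq_len(config@nClasses))
    storage.mode(codes) <- "integer"
    new("LandCoverRaster", codes = codes, cellSize = config@cellSize,
        origin = c(0, nr * config@cellSize),
        classLabels = stats::setNames(as.character(labels), names(labels)),
        nodataCode = 0L)
}

.makeBlocks <- function(config) {
    cs <- config@cellSize
    wCells <- config@rasterWidth %/% config@nBlocksX
    hCells <- config@rasterHeight %/% config@nBlocksY
    H <- config@rasterHeight * cs
    ids <- character(0); polys <- list(); cents <- NULL
    for (by in seq_len(config@nBlocksY)) {
        for (bx in seq_len(config@nBlocksX)) {
            x0 <- (bx - 1L) * wCells * cs; x1 <- bx * wCells * cs
            yT <- H - (by - 1L) * hCells * cs; yB <- H - by * hCells * cs
            id <- sprintf("B%02d_%02d", bx, by)
            ids <- c(ids, id)
            polys[[id]] <- matrix(c(x0, yB, x1, yB, x1, yT, x0, yT, x0, yB),
                                  ncol = 2, byrow = TRUE)
            cents <- rbind(cents, c((x0 + x1) / 2, (yB + yT) / 2))
        }
    }
    list(ids = ids, polys = polys, cents = cents,
         wCells = wCells, hCells = hCells)
}

# per-block class areas by direct tabulation over the block's cell ranges
.blockClassAreas <- function(codes, blocks, config) {
    nB <- length(blocks$ids)
    areas <- matrix(0, nB, config@nClasses,
                    dimnames = list(blocks$ids,
                                    as.character(seq_len(config@nClasses))))
    k <- 0L
    for (by in seq_len(config@nBlocksY)) {
        for (bx in seq_len(config@nBlocksX)) {
            k <- k + 1L
            rows <- ((by - 1L) * blocks$hCells + 1L):(by * blocks$hCells)
            cols <- ((bx - 1L) * blocks$wCells + 1L):(bx * blocks$wCells)
            tab <- tabulate(codes[rows, cols], nbins = config@nClasses)
            areas[k, ] <- tab * config@cellSize^2
        }
    }
    areas
}

.evalTruth <- function(config, centroids, classCodesChr) {
    tc <- config@trueCoefficients
    n <- nrow(centroids)
    if (is.numeric(tc)) {
        truth <- matrix(rep(tc, each = n), n, config@nClasses)
    } else {
        truth <- vapply(tc, function(f) {
            mapply(f, centroids[, 1], centroids[, 2])
        }, numeric(n))
        truth <- matrix(truth, n, config@nClasses)
    }
    if (any(truth < 0))
        stop("trueCoefficients must be non-negative everywhere")
    dimnames(truth) <- list(rownames(centroids), classCodesChr)
    truth
}

.makeRoads <- function(config) {
    sp <- config@roadSpacing
    W <- config@rasterWidth * config@cellSize
    H <- config@rasterHeight * config@cellSize
    xs <- seq(0, W, by = sp); ys <- seq(0, H, by = sp)
    nx <- length(xs); ny <- length(ys)
    nodeId <- function(i, j) (j - 1L) * nx + i
    from <- integer(0); to <- integer(0)
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
        if (i < nx) { from <- c(from, nodeId(i, j)); to <- c(to, nodeId(i + 1L, j)) }
        if (j < ny) { from <- c(from, nodeId(i, j)); to <- c(to, nodeId(i, j + 1L)) }
    }
    g <- igraph::make_empty_graph(n = nx * ny, directed = FALSE)
    g <- igraph::add_edges(g, rbind(from, to))
    nDrop <- floor(config@edgeDropFraction * igraph::ecount(g))
    order <- sample(igraph::ecount(g))
    dropped <- 0L
    # remove random non-bridge edges so the network stays connected
    igraph::E(g)$orig <- seq_len(igraph::ecount(g))
    for (e in order) {
        if (dropped >= nDrop) break
        eid <- which(igraph::E(g)$orig == e)
        if (!length(eid)) next
        if (eid %in% igraph::bridges(g)) next
        g <- igraph::delete_edges(g, eid)
        dropped <- dropped + 1L
    }
    ends <- igraph::ends(g, igraph::E(g))
    coords <- cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
    data.frame(x0 = coords[ends[, 1], 1], y0 = coords[ends[, 1], 2],
               x1 = coords[ends[, 2], 1], y1 = coords[ends[, 2], 2],
               length = sqrt((coords[ends[, 1], 1] - coords[ends[, 2], 1])^2 +
                             (coords[ends[, 1], 2] - coords[ends[, 2], 2])^2))
}

#' Generate a synthetic city
#'
#' Builds a complete synthetic study region: a patchy multi-class
#' land-cover raster (seeded multi-scale value noise thresholded at the
#' class-proportion quantiles), rectangular census blocks whose populations
#' follow p_i = sum_j coef_j(u_i, v_i) * S_ij + N(0, noiseSd), clamped at
#' zero, a connected road lattice with random gaps, and park entrances on
#' road nodes. The generating coefficients are returned as ground truth for
#' parameter-recovery tests.
#'
#' Deterministic for a fixed configuration (the seed lives in the config).
#'
#' @param config a \linkS4class{CityConfig}.
#' @return a \linkS4class{SyntheticCity}.
#' @examples
#' city <- generateCity(cityConfig(nBlocksX = 3, nBlocksY = 3,
#'                                 rasterWidth = 60, rasterHeight = 60))
#' city
#' @export
generateCity <- function(config) {
    stopifnot(is(config, "CityConfig"))
    validObject(config)
    set.seed(config@seed)
    lc <- .makeLandCover(config)
    blocks <- .makeBlocks(config)
    rownames(blocks$cents) <- blocks$ids
    classChr <- as.character(seq_len(config@nClasses))
    areas <- .blockClassAreas(lc@codes, blocks, config)
    truth <- .evalTruth(config, blocks$cents, classChr)
    popClean <- rowSums(truth * areas)
    noise <- if (config@noiseSd > 0)
        stats::rnorm(length(popClean), 0, config@noiseSd) else 0
    pop <- pmax(0, popClean + noise)
    zones <- new("ZoneSet", ids = blocks$ids, polygons = blocks$polys,
                 population = unname(pop), centroids = unname(blocks$cents))
    roads <- .makeRoads(config)
    nodes <- unique(rbind(as.matrix(roads[, c("x0", "y0")]),
                          as.matrix(roads[, c("x1", "y1")])))
    pick <- sample(nrow(nodes), min(config@nParks, nrow(nodes)))
    parks <- nodes[pick, , drop = FALSE]
    colnames(parks) <- c("x", "y")
    truthField <- new("CoefficientField", initial = truth,
                      provenance = "generator")
    new("SyntheticCity", landCover = lc, zones = zones, roads = roads,
        parkEntrances = parks, truth = truthField, config = config)
}

#' Perturb a land-cover classification
#'
#' Reassigns a fixed fraction of cells to a uniformly drawn different
#' class, emulating classification error, so that accuracy metrics
#' (confusion matrix, overall accuracy, kappa) can be exercised against a
#' known reference map. Exactly round(errorRate * nCells) cells change.
#'
#' @param raster a \linkS4class{LandCoverRaster}.
#' @param errorRate fraction of cells to corrupt, in [0, 1].
#' @param seed RNG seed (deterministic output per seed).
#' @return a \linkS4class{LandCoverRaster} with perturbed codes.
#' @examples
#' city <- generateCity(cityConfig(nBlocksX = 2, nBlocksY = 2,
#'                                 rasterWidth = 20, rasterHeight = 20))
#' noisy <- perturbClassification(city@landCover, 0.1, seed = 7)
#' mean(noisy@codes != city@landCover@codes)
#' @export
perturbClassification <- function(raster, errorRate, seed = 1L) {
    stopifnot(is(raster, "LandCoverRaster"))
    if (!is.numeric(errorRate) || errorRate < 0 || errorRate > 1)
        stop("errorRate must lie in [0, 1]")
    set.seed(seed)
    codes <- raster@codes
    allCodes <- as.integer(names(raster@classLabels))
    if (length(allCodes) < 2 && errorRate > 0)
        stop("cannot perturb a single-class raster")
    n <- length(codes)
    k <- round(errorRate * n)
    if (k > 0) {
        idx <- sample.int(n, k)
        for (i in idx) {
            others <- allCodes[allCodes != codes[i]]
            codes[i] <- if (length(others) == 1L) others else sample(others, 1L)
        }
    }
    out <- raster
    out@codes <- codes
    out
}
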