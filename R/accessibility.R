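#' @include AllGenerics.R
NULL

.nodeKey <- function(x, y) paste(round(x, 6), round(y, 6))

#' Build a walking-time network from road segments
#'
#' Nodes are the deduplicated segment endpoints (roads must be noded:
#' intersections share endpoints); edges carry their length (m) and
#' traversal time length / (speed * 60) minutes. Nodes of degree >= 3 are
#' intersections and carry the crossing delay, charged when a path passes
#' through them (not at the origin or terminal node). Zero-length segments
#' are dropped with a warning; duplicate segments collapse to the shorter.
#'
#' @param roads data.frame of segments with columns x0, y0, x1, y1 and
#'   optionally length (computed from the coordinates if absent).
#' @param speed walking speed, m/s (default 1).
#' @param intersectionPenalty crossing delay, minutes (default 0.5).
#' @return a \linkS4class{TravelNetwork} without sources; add park
#'   entrances with \code{\link{snapEntrances}}.
#' @examples
#' roads <- data.frame(x0 = 0, y0 = 0, x1 = 600, y1 = 0)
#' net <- buildNetwork(roads)          # one edge of 10 min
#' igraph::E(net@graph)$time
#' @export
buildNetwork <- function(roads, speed = 1, intersectionPenalty = 0.5) {
    stopifnot(is.data.frame(roads), speed > 0, intersectionPenalty >= 0)
    if (is.null(roads$length))
        roads$length <- sqrt((roads$x1 - roads$x0)^2 +
                             (roads$y1 - roads$y0)^2)
    zero <- roads$length <= 0
    if (any(zero)) {
        warning("dropping ", sum(zero), " zero-length segment(s)")
        roads <- roads[!zero, , drop = FALSE]
    }
    if (!nrow(roads)) stop("no usable road segments")
    kA <- .nodeKey(roads$x0, roads$y0)
    kB <- .nodeKey(roads$x1, roads$y1)
    keys <- unique(c(kA, kB))
    coords <- do.call(rbind, lapply(strsplit(keys, " "), as.numeric))
    colnames(coords) <- c("x", "y")
    g <- igraph::graph_from_edgelist(
        cbind(match(kA, keys), match(kB, keys)), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(keys) - igraph::vcount(g)))
    igraph::E(g)$length <- roads$length
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = list(length = "min"))
    igraph::E(g)$time <- igraph::E(g)$length / (speed * 60)
    new("TravelNetwork", graph = g, coords = coords,
        intersection = igraph::degree(g) >= 3, sources = integer(0),
        speed = speed, penalty = intersectionPenalty)
}

#' Attach park entrances to the network
#'
#' Each entrance is snapped to the nearest network node when one lies
#' within snapTol metres; otherwise the entrance is inserted by splitting
#' the nearest edge at the perpendicular foot point, so every source lies
#' on a network vertex.
#'
#' @param net a \linkS4class{TravelNetwork}.
#' @param points two-column coordinate matrix of entrances.
#' @param snapTol snap tolerance, metres (default 100).
#' @return the network with its sources set.
#' @export
snapEntrances <- function(net, points, snapTol = 100) {
    stopifnot(is(net, "TravelNetwork"))
    points <- rbind(points)
    g <- net@graph
    coords <- net@coords
    sources <- integer(0)
    for (q in seq_len(nrow(points))) {
        p <- as.numeric(points[q, 1:2])
        d <- sqrt((coords[, 1] - p[1])^2 + (coords[, 2] - p[2])^2)
        if (min(d) <= snapTol) {
            sources <- c(sources, which.min(d))
            next
        }
        # project onto every edge, split the nearest one
        ends <- igraph::ends(g, igraph::E(g))
        ax <- coords[ends[, 1], 1]; ay <- coords[ends[, 1], 2]
        bx <- coords[ends[, 2], 1]; by <- coords[ends[, 2], 2]
        len2 <- (bx - ax)^2 + (by - ay)^2
        t <- pmin(1, pmax(0, ((p[1] - ax) * (bx - ax) +
                              (p[2] - ay) * (by - ay)) / len2))
        fx <- ax + t * (bx - ax); fy <- ay + t * (by - ay)
        de <- sqrt((fx - p[1])^2 + (fy - p[2])^2)
        e <- which.min(de)
        newNode <- nrow(coords) + 1L
        coords <- rbind(coords, c(fx[e], fy[e]))
        g <- igraph::add_vertices(g, 1)
        L <- igraph::E(g)$length[e]
        la <- L * t[e]; lb <- L * (1 - t[e])
        u <- ends[e, 1]; v <- ends[e, 2]
        g <- igraph::delete_edges(g, e)
        g <- igraph::add_edges(g, c(u, newNode, newNode, v))
        ne <- igraph::ecount(g)
        igraph::E(g)$length[(ne - 1):ne] <- c(la, lb)
        igraph::E(g)$time <- igraph::E(g)$length / (net@speed * 60)
        sources <- c(sources, newNode)
    }
    out <- net
    out@graph <- g
    out@coords <- coords
    out@intersection <- igraph::degree(g) >= 3
    out@sources <- unique(as.integer(sources))
    out
}

#' Multi-source shortest travel times (service area, node part)
#'
#' Arrival time at every network node from the nearest park entrance:
#' edge traversal times plus the intersection delay for every interior
#' intersection crossed (the origin and the terminal node are not charged).
#' Implemented as a directed shortest-path problem in which each directed
#' edge carries the delay of its head node; the terminal node's charge is
#' then removed.
#'
#' @param net a \linkS4class{TravelNetwork} with at least one source.
#' @param threshold walking-time budget, minutes (default 15).
#' @return a \linkS4class{ServiceArea}.
#' @export
serviceArea <- function(net, threshold = 15) {
    stopifnot(is(net, "TravelNetwork"))
    if (!length(net@sources)) stop("network has no park-entrance sources")
    g <- net@graph
    ends <- igraph::ends(g, igraph::E(g))
    times <- igraph::E(g)$time
    pen <- net@penalty * net@intersection
    gd <- igraph::make_empty_graph(n = igraph::vcount(g), directed = TRUE)
    gd <- igraph::add_edges(gd, rbind(c(t(ends)), c(t(ends[, 2:1]))))
    # weight of u -> v charges v's crossing delay
    igraph::E(gd)$w <- c(rbind(times + pen[ends[, 2]],
                               times + pen[ends[, 1]]))
    D <- igraph::distances(gd, v = net@sources,
                           to = igraph::V(gd), mode = "out",
                           weights = igraph::E(gd)$w)
    arrive <- apply(D, 2, min)
    arrive <- pmax(0, arrive - pen)  # terminal node is not a crossing
    new("ServiceArea", times = unname(arrive),
        covered = unname(arrive <= threshold), threshold = threshold)
}

#' Per-cell coverage of the analysis grid
#'
#' Travel time of each analysis cell: the arrival time at the nearest
#' network node plus straight-line walking from the cell centre to that
#' node. Cells whose nearest node is beyond the off-network limit are
#' flagged unserved and uncovered.
#'
#' @param sa a \linkS4class{ServiceArea}.
#' @param net the \linkS4class{TravelNetwork} it came from.
#' @param grid a \linkS4class{GridDefinition} (or object carrying one,
#'   e.g. a \linkS4class{PopulationGrid}).
#' @param maxOffNetwork maximum straight-line approach, metres
#'   (default 500).
#' @return a \linkS4class{CoverageGrid}.
#' @export
gridCoverage <- function(sa, net, grid, maxOffNetwork = 500) {
    stopifnot(is(sa, "ServiceArea"), is(net, "TravelNetwork"))
    if (is(grid, "PopulationGrid")) grid <- grid@grid
    stopifnot(is(grid, "GridDefinition"))
    cs <- grid@cellSize
    cx <- grid@origin[1] + (seq_len(grid@ncol) - 0.5) * cs
    cy <- grid@origin[2] - (seq_len(grid@nrow) - 0.5) * cs
    centres <- cbind(rep(cx, each = grid@nrow), rep(cy, times = grid@ncol))
    nd <- net@coords
    times <- matrix(Inf, grid@nrow, grid@ncol)
    unserved <- matrix(FALSE, grid@nrow, grid@ncol)
    for (i in seq_len(nrow(centres))) {
        d <- sqrt((nd[, 1] - centres[i, 1])^2 + (nd[, 2] - centres[i, 2])^2)
        j <- which.min(d)
        if (d[j] > maxOffNetwork) {
            unserved[i] <- TRUE
        } else {
            times[i] <- sa@times[j] + d[j] / (net@speed * 60)
        }
    }
    new("CoverageGrid", times = times,
        covered = times <= sa@threshold & !unserved,
        unserved = unserved, grid = grid, threshold = sa@threshold)
}
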