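test_that("edge traversal time converts length and speed correctly", {
    net <- buildNetwork(data.frame(x0 = 0, y0 = 0, x1 = 600, y1 = 0))
    expect_equal(igraph::ecount(net@graph), 1)
    expect_equal(igraph::E(net@graph)$time, 10)
})

test_that("a plus-shaped crossing has one degree-4 intersection node", {
    roads <- data.frame(x0 = c(0, 100, 100, 100),
                        y0 = c(100, 100, 0, 100),
                        x1 = c(100, 200, 100, 100),
                        y1 = c(100, 100, 100, 200))
    net <- buildNetwork(roads)
    deg <- igraph::degree(net@graph)
    expect_equal(sum(deg == 4), 1)
    centre <- which(net@coords[, 1] == 100 & net@coords[, 2] == 100)
    expect_true(net@intersection[centre])
    expect_equal(sum(net@intersection), 1)
})

test_that("lattice node and edge counts match endpoint deduplication", {
    city <- generateCity(cityConfig(seed = 8L))
    net <- buildNetwork(city@roads)
    keys <- unique(c(paste(city@roads$x0, city@roads$y0),
                     paste(city@roads$x1, city@roads$y1)))
    expect_equal(igraph::vcount(net@graph), length(keys))
    expect_equal(igraph::ecount(net@graph), nrow(city@roads))
})

test_that("zero-length segments are dropped with a warning", {
    roads <- data.frame(x0 = c(0, 10), y0 = c(0, 0),
                        x1 = c(10, 10), y1 = c(0, 0))
    expect_warning(net <- buildNetwork(roads), "zero-length")
    expect_equal(igraph::ecount(net@graph), 1)
})

test_that("hand-computed path with an interior intersection delay", {
    # A -- B -- C with 600 m and 300 m edges; a stub at B raises its
    # degree to 3 so B is an intersection charged when passing through
    roads <- data.frame(x0 = c(0, 600, 600), y0 = c(0, 0, 0),
                        x1 = c(600, 900, 600), y1 = c(0, 0, 200))
    net <- buildNetwork(roads, speed = 1, intersectionPenalty = 0.5)
    net <- snapEntrances(net, cbind(0, 0))
    sa <- serviceArea(net, threshold = 15)
    iB <- which(net@coords[, 1] == 600 & net@coords[, 2] == 0)
    iC <- which(net@coords[, 1] == 900 & net@coords[, 2] == 0)
    expect_equal(sa@times[iB], 10)     # terminal node is not charged
    expect_equal(sa@times[iC], 15.5)   # 10 + 0.5 (crossing B) + 5
    expect_false(sa@covered[iC])
    expect_true(sa@covered[iB])
})

test_that("infinite threshold covers exactly the sources' component", {
    city <- generateCity(cityConfig(seed = 9L))
    net <- snapEntrances(buildNetwork(city@roads), city@parkEntrances)
    sa <- serviceArea(net, threshold = Inf)
    comp <- igraph::components(net@graph)$membership
    expect_setequal(which(sa@covered),
                    which(comp %in% unique(comp[net@sources])))
})

test_that("service-area times match exhaustive path enumeration", {
    set.seed(17)
    pts <- cbind(runif(10) * 1000, runif(10) * 1000)
    g0 <- igraph::sample_gnm(10, 16)
    while (!igraph::is_connected(g0)) g0 <- igraph::sample_gnm(10, 16)
    ed <- igraph::ends(g0, igraph::E(g0))
    roads <- data.frame(x0 = pts[ed[, 1], 1], y0 = pts[ed[, 1], 2],
                        x1 = pts[ed[, 2], 1], y1 = pts[ed[, 2], 2])
    net <- buildNetwork(roads, speed = 1, intersectionPenalty = 0.5)
    src <- c(1L, 4L)
    netS <- net; netS@sources <- src
    sa <- serviceArea(netS, threshold = 15)
    ends <- igraph::ends(net@graph, igraph::E(net@graph))
    oracle <- brutePathTimes(ends, igraph::E(net@graph)$time,
                             igraph::vcount(net@graph),
                             net@intersection, 0.5, src)
    expect_equal(sa@times, oracle, tolerance = 1e-9)
})

test_that("with zero penalty and one source times are textbook shortest paths", {
    city <- generateCity(cityConfig(seed = 10L))
    net <- buildNetwork(city@roads, intersectionPenalty = 0)
    net@sources <- 1L
    sa <- serviceArea(net)
    ref <- igraph::distances(net@graph, v = 1,
                             weights = igraph::E(net@graph)$time)
    expect_equal(sa@times, as.vector(ref), tolerance = 1e-12)
})

test_that("entrances snap to near nodes and split far edges", {
    roads <- data.frame(x0 = 0, y0 = 0, x1 = 1000, y1 = 0)
    net <- buildNetwork(roads)
    near <- snapEntrances(net, cbind(30, 40))        # 50 m from node 1
    expect_equal(near@sources, 1L)
    far <- snapEntrances(net, cbind(500, 200))       # 200 m off mid-edge
    expect_equal(igraph::vcount(far@graph), 3)
    expect_equal(sort(igraph::E(far@graph)$length), c(500, 500))
    expect_equal(far@coords[3, ], c(500, 0), ignore_attr = TRUE)
})

test_that("cell coverage adds the straight-line approach time", {
    roads <- data.frame(x0 = c(0, 600, 600), y0 = c(0, 0, 0),
                        x1 = c(600, 900, 600), y1 = c(0, 0, 200))
    net <- snapEntrances(buildNetwork(roads), cbind(0, 0))
    sa <- serviceArea(net, threshold = 15)
    grid <- new("GridDefinition", cellSize = 100, origin = c(0, 100),
                nrow = 1L, ncol = 9L)
    cov <- gridCoverage(sa, net, grid, maxOffNetwork = 500)
    # cell 9 centre (850, 50): nearest node C(900,0) at ~70.7 m
    iC <- which(net@coords[, 1] == 900 & net@coords[, 2] == 0)
    d <- sqrt(50^2 + 50^2)
    expect_equal(cov@times[1, 9], sa@times[iC] + d / 60)
    expect_false(cov@covered[1, 9])
    # cell centred 60 m from a node at 14.5 min arrives at 15.5
    grid1 <- new("GridDefinition", cellSize = 120, origin = c(840, 120),
                 nrow = 1L, ncol = 1L)
    sa2 <- sa; sa2@times[iC] <- 14.5
    cov2 <- gridCoverage(sa2, net, grid1)
    expect_equal(cov2@times[1, 1], 14.5 + 1.0)
    expect_false(cov2@covered[1, 1])
})

test_that("cells beyond the off-network limit are unserved", {
    net <- snapEntrances(buildNetwork(
        data.frame(x0 = 0, y0 = 0, x1 = 600, y1 = 0)), cbind(0, 0))
    sa <- serviceArea(net)
    grid <- new("GridDefinition", cellSize = 100, origin = c(0, 2000),
                nrow = 1L, ncol = 1L)
    cov <- gridCoverage(sa, net, grid, maxOffNetwork = 500)
    expect_true(cov@unserved[1, 1])
    expect_false(cov@covered[1, 1])
})

test_that("coverage is monotone in threshold and in added entrances", {
    city <- generateCity(cityConfig(seed = 11L))
    net <- snapEntrances(buildNetwork(city@roads), city@parkEntrances)
    t10 <- serviceArea(net, 10)@covered
    t15 <- serviceArea(net, 15)@covered
    t25 <- serviceArea(net, 25)@covered
    expect_true(all(t15[t10]))
    expect_true(all(t25[t15]))
    more <- snapEntrances(net, rbind(city@parkEntrances, c(2250, 2100)))
    saBase <- serviceArea(net, 15)
    saMore <- serviceArea(more, 15)
    expect_true(all(saMore@times[seq_along(saBase@times)] <=
                    saBase@times + 1e-9))
})

test_that("networks without sources are rejected", {
    net <- buildNetwork(data.frame(x0 = 0, y0 = 0, x1 = 600, y1 = 0))
    expect_error(serviceArea(net), "sources")
})
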