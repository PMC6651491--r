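fieldFrom <- function(init, provenance = "test") {
    new("CoefficientField", initial = init, provenance = provenance)
}

areasFrom <- function(A) new("ClassAreaTable", areas = A,
                             emptyZones = character(0))

test_that("block prediction is the coefficient-weighted area sum", {
    A <- matrix(1e6, 1, 1, dimnames = list("Z1", "1"))
    cf <- fieldFrom(matrix(0.01, 1, 1, dimnames = dimnames(A)))
    expect_equal(unname(predictBlockPopulation(cf, areasFrom(A))), 10000)

    cf0 <- fieldFrom(matrix(0, 3, 2, dimnames = list(paste0("Z", 1:3),
                                                     c("1", "2"))))
    A0 <- matrix(runif(6) * 1e5, 3, 2, dimnames = dimnames(cf0@initial))
    expect_equal(unname(predictBlockPopulation(cf0, areasFrom(A0))),
                 rep(0, 3))

    set.seed(5)
    init <- matrix(runif(12, 0, 0.02), 4, 3,
                   dimnames = list(paste0("Z", 1:4), c("1", "2", "3")))
    A3 <- matrix(runif(12) * 1e5, 4, 3, dimnames = dimnames(init))
    manual <- numeric(4)
    for (i in 1:4) for (j in 1:3)
        manual[i] <- manual[i] + init[i, j] * A3[i, j]
    expect_equal(unname(predictBlockPopulation(fieldFrom(init),
                                               areasFrom(A3))), manual)
})

test_that("relative error is signed percent with zero-population guard", {
    expect_equal(relativeError(100, 120), 20)
    expect_equal(relativeError(576000, 588000), 12000 / 576000 * 100)
    expect_equal(relativeError(250, 250), 0)
    expect_warning(e <- relativeError(c(0, 10), c(5, 11)), "zero population")
    expect_true(is.na(e[1]))
    expect_equal(e[2], 10)
})

test_that("rescaling restores block totals exactly and is idempotent", {
    A <- matrix(c(50, 30), 1, 2, dimnames = list("Z1", c("1", "2")))
    cf <- fieldFrom(matrix(2, 1, 2, dimnames = dimnames(A)))
    out <- rescaleCoefficients(cf, areasFrom(A), p = 100,
                               pHat = 80)
    expect_equal(unname(out@adjusted), matrix(2.5, 1, 2))

    set.seed(6)
    init <- matrix(runif(15, 0, 0.03), 5, 3,
                   dimnames = list(paste0("Z", 1:5), c("1", "2", "3")))
    A5 <- matrix(runif(15) * 2e5, 5, 3, dimnames = dimnames(init))
    p <- runif(5, 500, 5000)
    ar <- areasFrom(A5)
    f1 <- rescaleCoefficients(fieldFrom(init), ar, p)
    back <- predictBlockPopulation(f1, ar, which = "adjusted")
    expect_equal(unname(back), p, tolerance = 1e-9)
    # identity when already exact; second pass changes nothing
    f2 <- rescaleCoefficients(fieldFrom(f1@adjusted), ar, p)
    expect_equal(f2@adjusted, f1@adjusted, tolerance = 1e-12)
})

test_that("zero-prediction zones fall back to uniform density", {
    A <- matrix(c(1000, 4000), 1, 2, dimnames = list("Z1", c("1", "2")))
    cf <- fieldFrom(matrix(0, 1, 2, dimnames = dimnames(A)))
    expect_message(out <- rescaleCoefficients(cf, areasFrom(A), p = 250),
                   "uniformly")
    expect_equal(unname(predictBlockPopulation(out, areasFrom(A),
                                               "adjusted")), 250)
    expect_equal(unname(out@adjusted[1, ]), rep(250 / 5000, 2))
})

test_that("one zone collapsing to one cell reproduces its population", {
    r <- makeRaster(matrix(1L, 5, 5), cellSize = 30)
    z <- makeZones(rectZone("Z", 0, 0, 150, 150, population = 777))
    areas <- zonalClassAreas(r, z)
    cf <- fieldFrom(matrix(0.01, 1, 1, dimnames = list("Z", "1")))
    cf <- rescaleCoefficients(cf, areas, p = 777)
    pg <- gridPopulation(cf, gridClassAreas(r, z, gridSize = 150))
    expect_equal(sum(pg@values), 777)
    expect_equal(sum(pg@values > 0), 1L)
})

test_that("a uniform zone split over four equal cells gets quarters", {
    r <- makeRaster(matrix(1L, 10, 10), cellSize = 30)
    z <- makeZones(rectZone("Z", 0, 0, 300, 300, population = 1000))
    areas <- zonalClassAreas(r, z)
    cf <- rescaleCoefficients(fieldFrom(matrix(
        0.004, 1, 1, dimnames = list("Z", "1"))), areas, p = 1000)
    pg <- gridPopulation(cf, gridClassAreas(r, z, gridSize = 150))
    expect_equal(as.vector(pg@values), rep(250, 4))
})

test_that("grid inversion conserves mass and matches the pixel oracle", {
    city <- generateCity(smallCityConfig(noiseSd = 90, seed = 13L))
    areas <- zonalClassAreas(city@landCover, city@zones)
    fit <- fitOLS(areas, city@zones)
    cf <- coefficientField(fit, city@zones)
    cf <- rescaleCoefficients(cf, areas, city@zones@population)
    gca <- gridClassAreas(city@landCover, city@zones, gridSize = 150)
    pg <- gridPopulation(cf, gca)
    expect_equal(sum(pg@values), sum(city@zones@population),
                 tolerance = 1e-6)
    # per-cell pixel-level accumulation oracle
    r <- city@landCover
    zmap <- parkEquity:::.cellZoneMap(r, city@zones)
    ratio <- 150 / r@cellSize
    oracle <- matrix(0, pg@grid@nrow, pg@grid@ncol)
    for (rr in seq_len(nrow(r@codes))) for (cc in seq_len(ncol(r@codes))) {
        zi <- zmap[rr, cc]
        if (is.na(zi) || r@codes[rr, cc] == r@nodataCode) next
        gr <- (rr - 1) %/% ratio + 1
        gc <- (cc - 1) %/% ratio + 1
        oracle[gr, gc] <- oracle[gr, gc] +
            cf@adjusted[zi, as.character(r@codes[rr, cc])] * r@cellSize^2
    }
    expect_equal(pg@values, oracle, tolerance = 1e-9)
})

test_that("density view converts persons/cell to persons/km^2", {
    grid <- new("GridDefinition", cellSize = 150, origin = c(0, 300),
                nrow = 2L, ncol = 2L)
    pg <- new("PopulationGrid", values = matrix(3617, 2, 2), grid = grid,
              studyMask = matrix(TRUE, 2, 2))
    expect_equal(densityPerKm2(pg)[1, 1], 3617 / 0.0225)
})

test_that("error report bins absolute errors like the street-scale table", {
    rep0 <- errorReport(rep(100, 4), rep(100, 4))
    expect_equal(rep0@bins, c(4L, 0L, 0L, 0L))
    expect_equal(rep0@meanAbs, 0)

    repx <- errorReport(rep(100, 4), c(105, 115, 125, 150))
    expect_equal(repx@bins, c(1L, 1L, 1L, 1L))
    expect_equal(repx@meanAbs, mean(c(5, 15, 25, 50)))

    set.seed(14)
    p <- runif(89, 100, 10000)
    ph <- p * runif(89, 0.5, 1.6)
    repr <- errorReport(p, ph)
    ae <- sort(abs((ph - p) / p * 100))
    expect_equal(repr@bins, c(sum(ae <= 10), sum(ae > 10 & ae <= 20),
                              sum(ae > 20 & ae <= 30), sum(ae > 30)))
    expect_equal(sum(repr@bins), 89L)
})
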