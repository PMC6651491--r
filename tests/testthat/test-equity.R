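# small helpers shared by the overlay tests
popOn <- function(values, cellSize = 150, mask = NULL) {
    grid <- new("GridDefinition", cellSize = cellSize,
                origin = c(0, nrow(values) * cellSize),
                nrow = nrow(values), ncol = ncol(values))
    if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
    new("PopulationGrid", values = values, grid = grid, studyMask = mask)
}

covOn <- function(covered, pop, threshold = 15) {
    new("CoverageGrid", times = ifelse(covered, 1, 100),
        covered = covered, unserved = !covered & FALSE, grid = pop@grid,
        threshold = threshold)
}

test_that("overlay totals are conserved under full and null coverage", {
    vals <- matrix(runif(16, 0, 500), 4, 4)
    pop <- popOn(vals)
    allCov <- overlayCoverage(pop, covOn(matrix(TRUE, 4, 4), pop))
    expect_equal(allCov@uncoveredPopulation, 0)
    expect_equal(allCov@coveredFractionPct, 100)
    expect_equal(allCov@areaFractionPct, 100)
    none <- overlayCoverage(pop, covOn(matrix(FALSE, 4, 4), pop))
    expect_equal(none@uncoveredPopulation, sum(vals))
    expect_equal(none@coveredPopulation, 0)
})

test_that("random-mask overlay matches a cellwise loop oracle", {
    set.seed(19)
    vals <- matrix(runif(36, 0, 800), 6, 6)
    mask <- matrix(runif(36) < 0.6, 6, 6)
    pop <- popOn(vals)
    rep <- overlayCoverage(pop, covOn(mask, pop))
    covered <- 0; uncovered <- 0
    for (i in 1:6) for (j in 1:6) {
        if (mask[i, j]) covered <- covered + vals[i, j]
        else uncovered <- uncovered + vals[i, j]
    }
    expect_equal(rep@coveredPopulation, covered)
    expect_equal(rep@uncoveredPopulation, uncovered)
    expect_equal(rep@lowAccess@values, vals * !mask)
    expect_equal(rep@coveredPopulation + rep@uncoveredPopulation,
                 sum(vals))
    expect_equal(rep@coveredAreaKm2, sum(mask) * 0.0225)
})

test_that("grid mismatch is rejected", {
    pop <- popOn(matrix(1, 4, 4))
    other <- popOn(matrix(1, 5, 5))
    expect_error(overlayCoverage(pop, covOn(matrix(TRUE, 5, 5), other)),
                 "differ")
})

test_that("a single street absorbs the whole uncovered total", {
    vals <- matrix(runif(16, 0, 300), 4, 4)
    pop <- popOn(vals)
    cov <- covOn(matrix(runif(16) < 0.5, 4, 4), pop)
    streets <- makeZones(rectZone("S", 0, 0, 600, 600))
    st <- streetEquity(pop, cov, streets)
    rep <- overlayCoverage(pop, cov)
    expect_equal(st$uncovered, rep@uncoveredPopulation)
    expect_equal(st$population, sum(vals))
})

test_that("mirror-image streets over a symmetric city split evenly", {
    vals <- matrix(5, 4, 4)
    mask <- matrix(FALSE, 4, 4); mask[, 1:2] <- TRUE
    mask[, 3:4] <- mask[, 2:1]          # mirror-symmetric coverage
    pop <- popOn(vals)
    cov <- covOn(mask, pop)
    streets <- makeZones(rectZone("W", 0, 0, 300, 600),
                         rectZone("E", 300, 0, 600, 600))
    st <- streetEquity(pop, cov, streets)
    expect_equal(st$uncovered[1], st$uncovered[2])
    expect_equal(st$population[1], st$population[2])
})

test_that("street sums match a loop oracle on a 9-street city", {
    set.seed(23)
    vals <- matrix(runif(36, 0, 900), 6, 6)
    mask <- matrix(runif(36) < 0.5, 6, 6)
    pop <- popOn(vals)
    cov <- covOn(mask, pop)
    zs <- list()
    for (sy in 0:2) for (sx in 0:2)
        zs[[length(zs) + 1]] <- rectZone(sprintf("S%d%d", sx, sy),
                                         sx * 300, sy * 300,
                                         (sx + 1) * 300, (sy + 1) * 300)
    streets <- do.call(makeZones, zs)
    st <- streetEquity(pop, cov, streets)
    # oracle: explicit cell-centre lookup
    oracleTot <- stats::setNames(numeric(9), streets@ids)
    oracleUnc <- oracleTot
    for (r in 1:6) for (cc in 1:6) {
        cx <- (cc - 0.5) * 150; cy <- 900 - (r - 0.5) * 150
        sx <- cx %/% 300; sy <- cy %/% 300
        id <- sprintf("S%d%d", sx, sy)
        oracleTot[id] <- oracleTot[id] + vals[r, cc]
        if (!mask[r, cc]) oracleUnc[id] <- oracleUnc[id] + vals[r, cc]
    }
    expect_equal(st$population, unname(oracleTot[st$street_id]))
    expect_equal(st$uncovered, unname(oracleUnc[st$street_id]))
    expect_equal(sum(st$uncovered), sum(vals * !mask))
})

test_that("equity classes follow the thresholds", {
    expect_equal(classifyEquity(0), "equitable")
    got <- classifyEquity(c(0, 5, 5e3, 5e4, 2e5),
                          thresholds = c(1e4, 1e5))
    expect_equal(got, c("equitable", "unequal", "unequal", "very unequal",
                        "extremely unequal"))
    expect_error(classifyEquity(c(1, 2), thresholds = c(5, 5)),
                 "increasing")
    # identical nonzero streets land in one class
    same <- classifyEquity(rep(1000, 4))
    expect_equal(length(unique(same)), 1L)
})

test_that("raising the threshold never raises street uncovered counts", {
    city <- generateCity(cityConfig(seed = 15L))
    areas <- zonalClassAreas(city@landCover, city@zones)
    fit <- fitOLS(areas, city@zones)
    cf <- rescaleCoefficients(coefficientField(fit, city@zones), areas,
                              city@zones@population)
    pg <- gridPopulation(cf, gridClassAreas(city@landCover, city@zones, 150))
    net <- snapEntrances(buildNetwork(city@roads), city@parkEntrances)
    for (pair in list(c(10, 15), c(15, 25))) {
        covA <- gridCoverage(serviceArea(net, pair[1]), net, pg@grid)
        covB <- gridCoverage(serviceArea(net, pair[2]), net, pg@grid)
        stA <- streetEquity(pg, covA, city@zones)
        stB <- streetEquity(pg, covB, city@zones)
        expect_true(all(stB$uncovered <= stA$uncovered + 1e-9))
    }
})
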