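# a hand-built area table / zone pair for exact regression checks
toyData <- function(X, y, coords = NULL) {
    n <- nrow(X)
    ids <- sprintf("Z%02d", seq_len(n))
    if (is.null(coords))
        coords <- cbind(seq_len(n) * 100, rep(0, n))
    zones <- new("ZoneSet", ids = ids,
                 polygons = stats::setNames(replicate(n, matrix(
                     c(0, 0, 1, 0, 1, 1, 0, 1, 0, 0), ncol = 2,
                     byrow = TRUE), simplify = FALSE), ids),
                 population = y, centroids = coords)
    dimnames(X) <- list(ids, as.character(seq_len(ncol(X))))
    list(areas = new("ClassAreaTable", areas = X,
                     emptyZones = character(0)),
         zones = zones)
}

test_that("spearman screen recovers monotone orderings and handles ties", {
    set.seed(1)
    x <- runif(12) * 1e5
    d <- toyData(cbind(x, rev(sort(x))), y = sort(x))
    scr <- spearmanScreen(d$areas, d$zones)
    expect_equal(scr$rho[1], cor(x, sort(x), method = "spearman"))
    expect_equal(scr$rho[2], -1)
    # ties: rank-then-Pearson oracle
    xt <- c(1, 2, 2, 3, 3, 3, 4, 5, 5, 6) * 1000
    yt <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9) * 10
    dt <- toyData(cbind(xt, runif(10)), yt)
    scrt <- spearmanScreen(dt$areas, dt$zones)
    expect_equal(scrt$rho[1], cor(rank(xt), rank(yt)))
    # zero-variance column is flagged, not fatal
    dz <- toyData(cbind(x, rep(5, 12)), y = sort(x))
    expect_warning(scrz <- spearmanScreen(dz$areas, dz$zones),
                   "zero area variance")
    expect_true(is.na(scrz$rho[2]))
})

test_that("no-intercept OLS fits exact linear data exactly", {
    x <- c(10, 20, 30, 40, 50) * 1000
    d <- toyData(cbind(x), y = 2 * x)
    fit <- fitOLS(d$areas, d$zones)
    expect_equal(unname(fit@coefficients), 2, tolerance = 1e-12)
    expect_equal(fit@r2, 1)
    expect_equal(fit@intercept, 0)
})

test_that("OLS recovers the generating coefficients at zero noise", {
    city <- generateCity(smallCityConfig(noiseSd = 0))
    areas <- zonalClassAreas(city@landCover, city@zones)
    fit <- fitOLS(areas, city@zones)
    truth <- city@truth@initial[1, ]
    expect_equal(fit@coefficients[names(truth)], truth, tolerance = 1e-8)
})

test_that("perfectly collinear predictors raise a collinearity error", {
    x <- runif(8) * 1e4
    d <- toyData(cbind(x, x, runif(8)), y = x)
    expect_error(fitOLS(d$areas, d$zones), "collinear")
})

test_that("VIF is 1 for orthogonal predictors and infinite under collinearity", {
    x1 <- rep(c(1, -1), 6) + 2
    x2 <- rep(c(1, 1, -1, -1), 3) + 2   # orthogonal to x1 after centring
    d <- toyData(cbind(x1, x2) * 1000, y = runif(12) * 100)
    fit <- fitOLS(d$areas, d$zones)
    expect_equal(unname(fit@vif), c(1, 1))
})

test_that("GWR with uniform kernel at full bandwidth equals OLS", {
    city <- generateCity(smallCityConfig(noiseSd = 80, seed = 3L))
    areas <- zonalClassAreas(city@landCover, city@zones)
    ols <- fitOLS(areas, city@zones)
    gwr <- fitGWR(areas, city@zones, bandwidth = nZones(city@zones),
                  kernel = "uniform")
    for (i in seq_len(nZones(city@zones)))
        expect_equal(unname(gwr@local[i, ]), unname(ols@coefficients),
                     tolerance = 1e-8)
    expect_equal(gwr@trS, length(ols@coefficients), tolerance = 1e-8)
})

test_that("GWR local fits equal explicit per-zone weighted least squares", {
    city <- generateCity(cityConfig(seed = 9L))
    areas <- zonalClassAreas(city@landCover, city@zones)
    bw <- 20L
    gwr <- fitGWR(areas, city@zones, bandwidth = bw)
    X <- classAreas(areas)
    y <- city@zones@population
    D <- as.matrix(dist(city@zones@centroids))
    for (i in seq_len(nrow(X))) {
        b <- sort(D[i, ])[bw]
        w <- ifelse(D[i, ] < b, (1 - (D[i, ] / b)^2)^2, 0)
        expect_equal(unname(gwr@local[i, ]),
                     unname(bruteWLS(X, y, w)), tolerance = 1e-8)
    }
})

test_that("GWR tracks a smooth spatially varying coefficient surface", {
    city <- generateCity(gradientCityConfig(noiseSd = 0, seed = 2L))
    areas <- zonalClassAreas(city@landCover, city@zones)
    bw <- selectBandwidth(areas, city@zones)
    gwr <- fitGWR(areas, city@zones, bandwidth = bw)
    expect_lt(bw, nZones(city@zones))  # varying truth pulls bandwidth down
    for (p in colnames(gwr@local))
        expect_gt(cor(gwr@local[, p], city@truth@initial[, p]), 0.9)
})

test_that("bandwidth selection prefers the global limit under constant truth", {
    city <- generateCity(smallCityConfig(noiseSd = 50, seed = 12L))
    areas <- zonalClassAreas(city@landCover, city@zones)
    n <- nZones(city@zones)
    bw <- selectBandwidth(areas, city@zones, c("1", "2", "3"),
                          candidates = c(6L, 7L, 8L, 9L, n))
    expect_gte(bw, n - 1L)
    single <- selectBandwidth(areas, city@zones, c("1", "2", "3"),
                              candidates = 7L)
    expect_equal(as.integer(single), 7L)
    expect_error(selectBandwidth(areas, city@zones, c("1", "2"),
                                 candidates = integer(0)), "empty")
})

test_that("model comparison applies the AIC-gap rule and ties on identical fits", {
    city <- generateCity(smallCityConfig(noiseSd = 60, seed = 21L))
    areas <- zonalClassAreas(city@landCover, city@zones)
    ols <- fitOLS(areas, city@zones)
    # uniform kernel at full bandwidth reproduces OLS: identical residuals
    gwr <- fitGWR(areas, city@zones, bandwidth = nZones(city@zones),
                  kernel = "uniform")
    cmp <- compareModels(ols, gwr, city@zones)
    expect_equal(cmp@deltaAIC, 0, tolerance = 1e-6)
    expect_equal(cmp@preferred, "indistinguishable")
    # a 2.9-point gap is still indistinguishable under the > 3 rule
    fake <- gwr
    fake@aicc <- gwr@aicc + 2.9
    expect_equal(compareModels(ols, fake, city@zones)@preferred,
                 "indistinguishable")
    fake@aicc <- gwr@aicc + 3.5
    expect_equal(compareModels(ols, fake, city@zones)@preferred, "ols")
})
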