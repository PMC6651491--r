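#' @include AllGenerics.R
NULL

.designMatrix <- function(areas, predictors, noIntercept) {
    A <- classAreas(areas)
    if (is.null(predictors)) predictors <- colnames(A)
    predictors <- as.character(predictors)
    missing <- setdiff(predictors, colnames(A))
    if (length(missing))
        stop("predictor classes absent from the area table: ",
             paste(missing, collapse = ", "))
    X <- A[, predictors, drop = FALSE]
    if (any(colSums(abs(X)) == 0))
        stop("all-zero predictor columns: ",
             paste(predictors[colSums(abs(X)) == 0], collapse = ", "))
    if (!noIntercept) X <- cbind(`(Intercept)` = 1, X)
    X
}

.checkAligned <- function(areas, zones) {
    if (!identical(zoneIds(areas), zoneIds(zones)))
        stop("area table and zone set refer to different zones")
}

#' Spearman screening of land-cover classes
#'
#' Rank correlation of each class area with the zone populations, the
#' variable-screening step run before model building. The p-value uses the
#' large-sample t approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2
#' degrees of freedom. Classes with zero area variance get NA with a
#' warning.
#'
#' @param areas a \linkS4class{ClassAreaTable}.
#' @param zones the matching \linkS4class{ZoneSet} (>= 3 zones).
#' @return data.frame with columns class, label-free rho, p, sig05, sig01.
#' @examples
#' city <- generateCity(cityConfig(nBlocksX = 3, nBlocksY = 3,
#'                                 rasterWidth = 60, rasterHeight = 60))
#' areas <- zonalClassAreas(city@landCover, city@zones)
#' spearmanScreen(areas, city@zones)
#' @export
spearmanScreen <- function(areas, zones) {
    .checkAligned(areas, zones)
    A <- classAreas(areas)
    p <- zones@population
    n <- length(p)
    if (n < 3) stop("need at least 3 zones")
    res <- lapply(colnames(A), function(cl) {
        x <- A[, cl]
        if (stats::sd(x) == 0) {
            warning("class ", cl, " has zero area variance; rho undefined")
            return(data.frame(class = cl, rho = NA_real_, p = NA_real_,
                              sig05 = NA, sig01 = NA))
        }
        rho <- stats::cor(x, p, method = "spearman")
        pv <- if (abs(rho) >= 1) 0 else {
            tstat <- rho * sqrt((n - 2) / (1 - rho^2))
            2 * stats::pt(-abs(tstat), df = n - 2)
        }
        data.frame(class = cl, rho = rho, p = pv,
                   sig05 = pv < 0.05, sig01 = pv < 0.01)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Global OLS dasymetric regression
#'
#' Least-squares fit of zone population on per-class areas,
#' p_i = sum_j a_j S_ij (+ b). By default the intercept is fixed at zero
#' ("no land without population"). Reports R^2 and adjusted R^2 (both
#' against the centred total sum of squares so that global and local models
#' are comparable), the Gaussian-likelihood AIC
#' n log(RSS/n) + 2(k + 1), and variance inflation factors from
#' intercept-bearing auxiliary regressions among the predictors.
#'
#' @param areas a \linkS4class{ClassAreaTable}.
#' @param zones the matching \linkS4class{ZoneSet}.
#' @param predictors class codes to use (default all columns).
#' @param noIntercept fix the constant at zero (default TRUE).
#' @return an \linkS4class{OLSFit}.
#' @examples
#' city <- generateCity(cityConfig(nBlocksX = 3, nBlocksY = 3,
#'                                 rasterWidth = 60, rasterHeight = 60,
#'                                 noiseSd = 0))
#' areas <- zonalClassAreas(city@landCover, city@zones)
#' fitOLS(areas, city@zones)
#' @export
fitOLS <- function(areas, zones, predictors = NULL, noIntercept = TRUE) {
    .checkAligned(areas, zones)
    X <- .designMatrix(areas, predictors, noIntercept)
    y <- zones@population
    n <- length(y)
    k <- ncol(X)
    if (n < k + 2) stop("need at least ", k + 2, " zones for ", k,
                        " parameters")
    qrX <- qr(X)
    if (qrX$rank < k) {
        bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
        stop("collinear predictor classes: ", paste(bad, collapse = ", "))
    }
    fit <- stats::lm.fit(X, y)
    coefs <- fit$coefficients
    fitted <- drop(X %*% coefs)
    resid <- y - fitted
    rss <- sum(resid^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    adjR2 <- 1 - (1 - r2) * (n - 1) / (n - k)
    aic <- n * log(rss / n) + 2 * (k + 1)
    preds <- setdiff(colnames(X), "(Intercept)")
    vif <- if (length(preds) < 2) {
        stats::setNames(rep(1, length(preds)), preds)
    } else {
        vapply(preds, function(pj) {
            Z <- cbind(1, X[, setdiff(preds, pj), drop = FALSE])
            aux <- stats::lm.fit(Z, X[, pj])
            r2a <- 1 - sum(aux$residuals^2) /
                sum((X[, pj] - mean(X[, pj]))^2)
            if (r2a >= 1 - 1e-12) Inf else 1 / (1 - r2a)
        }, numeric(1))
    }
    new("OLSFit",
        coefficients = coefs[preds],
        intercept = if (noIntercept) 0 else unname(coefs["(Intercept)"]),
        residuals = unname(resid), fitted = unname(fitted),
        r2 = r2, adjR2 = adjR2, aic = aic, vif = vif,
        predictors = preds, noIntercept = noIntercept)
}

# adaptive kernel weights for location i: bandwidth-th nearest-neighbour
# distance (self included) defines the local radius
.gwrWeights <- function(d, bandwidth, kernel) {
    b <- sort(d, partial = bandwidth)[bandwidth]
    if (b <= 0) stop("duplicate zone centroids: adaptive bandwidth radius is 0")
    switch(kernel,
        bisquare = ifelse(d < b, (1 - (d / b)^2)^2, 0),
        uniform = as.numeric(d <= b),
        stop("unknown kernel: ", kernel))
}

#' Geographically weighted regression of population on class areas
#'
#' Local weighted least squares at every zone centroid under an adaptive
#' kernel: the weight of zone j in the fit at zone i is
#' w_ij = (1 - (d_ij / b_i)^2)^2 for d_ij < b_i and 0 beyond, where b_i is
#' the distance to the bandwidth-th nearest neighbour of i (bisquare; a
#' uniform kernel is available, under which bandwidth = n reproduces the
#' global OLS fit). The model is fitted without an intercept by default,
#' matching the dasymetric constraint; set noIntercept = FALSE for a local
#' intercept. Reports the hat-matrix trace tr(S) (effective parameters)
#' and the corrected information criterion
#' AICc = n log(RSS/n) + n log(2 pi) + n (n + tr(S)) / (n - 2 - tr(S)).
#'
#' @param areas a \linkS4class{ClassAreaTable}.
#' @param zones the matching \linkS4class{ZoneSet}.
#' @param predictors class codes to use (default all columns).
#' @param bandwidth adaptive neighbour count (>= predictors + 2).
#' @param kernel "bisquare" (default) or "uniform".
#' @param noIntercept fix the local constant at zero (default TRUE).
#' @return a \linkS4class{GWRFit}.
#' @seealso \code{\link{selectBandwidth}}
#' @export
fitGWR <- function(areas, zones, predictors = NULL, bandwidth,
                   kernel = c("bisquare", "uniform"), noIntercept = TRUE) {
    .checkAligned(areas, zones)
    kernel <- match.arg(kernel)
    X <- .designMatrix(areas, predictors, noIntercept)
    y <- zones@population
    n <- length(y)
    k <- ncol(X)
    bandwidth <- as.integer(bandwidth)
    if (bandwidth < k + 2)
        stop("bandwidth must be at least predictors + 2 neighbours")
    if (bandwidth > n) stop("bandwidth exceeds the zone count")
    D <- as.matrix(stats::dist(zones@centroids))
    local <- matrix(NA_real_, n, k, dimnames = list(zones@ids, colnames(X)))
    fitted <- numeric(n)
    trS <- 0
    for (i in seq_len(n)) {
        w <- .gwrWeights(D[i, ], bandwidth, kernel)
        Xw <- X * w
        A <- crossprod(X, Xw)
        ok <- TRUE
        beta <- tryCatch(solve(A, crossprod(Xw, y)),
                         error = function(e) { ok <<- FALSE; NULL })
        if (!ok)
            stop("singular local fit at zone ", zones@ids[i],
                 ": too few effective neighbours for ", k, " parameters")
        local[i, ] <- beta
        fitted[i] <- sum(X[i, ] * beta)
        # hat-row diagonal: x_i' (X'WX)^{-1} X'W e_i
        hi <- drop(X[i, ] %*% solve(A, t(Xw)))
        trS <- trS + unname(hi[i])
    }
    resid <- y - fitted
    rss <- sum(resid^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    adjR2 <- if (n - trS > 1) 1 - (1 - r2) * (n - 1) / (n - trS) else NA_real_
    aicc <- if (n - 2 - trS > 0)
        n * log(rss / n) + n * log(2 * pi) + n * (n + trS) / (n - 2 - trS)
    else Inf
    new("GWRFit", local = local, residuals = unname(resid),
        fitted = unname(fitted), bandwidth = bandwidth, kernel = kernel,
        trS = trS, aicc = aicc, r2 = r2, adjR2 = adjR2,
        predictors = setdiff(colnames(X), "(Intercept)"),
        noIntercept = noIntercept)
}

#' Adaptive-bandwidth selection by minimum AICc
#'
#' Exhaustively evaluates the GWR AICc over a ladder of candidate
#' neighbour counts and returns the minimiser; ties are broken toward the
#' larger (smoother) bandwidth. With spatially constant true coefficients
#' the selected bandwidth sits at or near the top of the ladder (the
#' global model is optimal); sharply varying coefficient surfaces pull it
#' down.
#'
#' @param areas a \linkS4class{ClassAreaTable}.
#' @param zones the matching \linkS4class{ZoneSet}.
#' @param predictors class codes to use (default all columns).
#' @param candidates integer vector of neighbour counts within
#'   [predictors + 2, n].
#' @param kernel kernel name, see \code{\link{fitGWR}}.
#' @param noIntercept see \code{\link{fitGWR}}.
#' @return the selected neighbour count (integer), with the evaluated
#'   ladder and AICc values attached as attribute "profile".
#' @export
selectBandwidth <- function(areas, zones, predictors = NULL,
                            candidates = NULL,
                            kernel = c("bisquare", "uniform"),
                            noIntercept = TRUE) {
    kernel <- match.arg(kernel)
    n <- nZones(zones)
    k <- length(if (is.null(predictors)) classCodes(areas) else predictors) +
        as.integer(!noIntercept)
    if (is.null(candidates)) {
        lo <- k + 2L
        candidates <- unique(round(seq(lo, n, length.out = min(12, n - lo + 1))))
    }
    candidates <- sort(unique(as.integer(candidates)))
    if (!length(candidates)) stop("empty candidate range")
    if (any(candidates < k + 2L) || any(candidates > n))
        stop("candidates must lie in [predictors + 2, n]")
    aiccs <- vapply(candidates, function(bw) {
        # a bandwidth whose local fit is singular at some zone is infeasible
        tryCatch(fitGWR(areas, zones, predictors, bw, kernel,
                        noIntercept)@aicc,
                 error = function(e) Inf)
    }, numeric(1))
    if (all(!is.finite(aiccs)))
        stop("no feasible bandwidth in the candidate range")
    best <- max(candidates[aiccs == min(aiccs)])
    attr(best, "profile") <- data.frame(bandwidth = candidates, aicc = aiccs)
    best
}

#' Compare the global and local population models
#'
#' Applies the comparison rules used for the dasymetric model choice: the
#' AIC difference (only a gap larger than 3 distinguishes the models),
#' adjusted R^2 of both fits, and the spatial autocorrelation of each
#' model's residuals (Moran's I with z and p). A well-behaved local model
#' has higher adjusted R^2 and residuals closer to spatial randomness.
#'
#' To put the two criteria on one scale, the global model's information
#' criterion is recomputed in the same corrected Gaussian form used for
#' the local model, with its hat-matrix trace equal to the parameter
#' count; two models with identical residuals and equal effective
#' parameters then tie exactly.
#'
#' @param ols an \linkS4class{OLSFit}.
#' @param gwr a \linkS4class{GWRFit} on the same zones.
#' @param zones the \linkS4class{ZoneSet} both models were fitted on.
#' @param scheme Moran weight scheme, see \code{\link{moranI}}.
#' @return a \linkS4class{ModelComparison}.
#' @export
compareModels <- function(ols, gwr, zones, scheme = "idw") {
    stopifnot(is(ols, "OLSFit"), is(gwr, "GWRFit"))
    if (length(ols@residuals) != nZones(zones) ||
        length(gwr@residuals) != nZones(zones))
        stop("fits and zone set refer to different zones")
    n <- length(ols@residuals)
    k <- length(ols@predictors) + as.integer(!ols@noIntercept)
    rssOls <- sum(ols@residuals^2)
    olsAicc <- n * log(rssOls / n) + n * log(2 * pi) +
        n * (n + k) / (n - 2 - k)
    delta <- olsAicc - gwr@aicc
    preferred <- if (abs(delta) <= 3) "indistinguishable"
        else if (delta > 0) "gwr" else "ols"
    mOls <- moranI(ols@residuals, zones, scheme = scheme)
    mGwr <- moranI(gwr@residuals, zones, scheme = scheme)
    new("ModelComparison", deltaAIC = delta, preferred = preferred,
        olsAdjR2 = ols@adjR2, gwrAdjR2 = gwr@adjR2,
        olsMoran = mOls, gwrMoran = mGwr)
}
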