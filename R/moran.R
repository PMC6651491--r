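#' @include AllGenerics.R
NULL

# queen contiguity through bounding-box touch tests; exact for rectangular
# zone tessellations (corner contact counts as adjacency)
.queenWeights <- function(zones, tol = 1e-6) {
    n <- length(zones@ids)
    bb <- t(vapply(zones@polygons, function(p)
        c(range(p[, 1]), range(p[, 2])), numeric(4)))
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        touchX <- bb[i, 1] <= bb[j, 2] + tol && bb[j, 1] <= bb[i, 2] + tol
        touchY <- bb[i, 3] <= bb[j, 4] + tol && bb[j, 3] <= bb[i, 4] + tol
        if (touchX && touchY) W[i, j] <- W[j, i] <- 1
    }
    W
}

.idwWeights <- function(zones) {
    D <- as.matrix(stats::dist(zones@centroids))
    if (any(D[upper.tri(D)] == 0))
        stop("duplicate zone centroids break inverse-distance weights")
    W <- 1 / D
    diag(W) <- 0
    W
}

#' Global Moran's I of per-zone values
#'
#' I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z the centred
#' values. Inference uses the randomization (permutation-moment) variance
#' and a two-sided normal approximation; an empirical permutation null can
#' be requested in addition. The expectation under spatial randomness is
#' -1/(n-1). Weights are row-standardized.
#'
#' @param values numeric per-zone values (e.g. model residuals); must not
#'   be constant.
#' @param zones a \linkS4class{ZoneSet} (>= 4 zones).
#' @param scheme "idw" (inverse distance between centroids, the default)
#'   or "queen" (contiguity); alternatively supply a weight matrix via W.
#' @param W optional n x n non-negative spatial weight matrix (zero
#'   diagonal); overrides scheme.
#' @param nperm number of value permutations for an empirical null
#'   (0 = none).
#' @return a \linkS4class{MoranResult}.
#' @examples
#' city <- generateCity(cityConfig(nBlocksX = 4, nBlocksY = 4,
#'                                 rasterWidth = 40, rasterHeight = 40))
#' moranI(city@zones@centroids[, 1], city@zones)  # smooth gradient: I > 0
#' @export
moranI <- function(values, zones, scheme = c("idw", "queen"), W = NULL,
                   nperm = 0) {
    n <- length(values)
    if (n < 4) stop("need at least 4 zones")
    if (stats::sd(values) == 0) stop("values are constant; Moran's I undefined")
    if (is.null(W)) {
        scheme <- match.arg(scheme)
        W <- switch(scheme, idw = .idwWeights(zones),
                    queen = .queenWeights(zones))
    } else {
        scheme <- "custom"
        if (!is.matrix(W) || any(dim(W) != n) || any(W < 0))
            stop("W must be a non-negative n x n matrix")
        diag(W) <- 0
    }
    rs <- rowSums(W)
    if (any(rs == 0)) stop("zones with no neighbours under this scheme")
    W <- W / rs
    z <- values - mean(values)
    m2 <- sum(z^2)
    S0 <- sum(W)
    I <- (n / S0) * drop(z %*% W %*% z) / m2
    EI <- -1 / (n - 1)
    # randomization moments (Cliff & Ord)
    S1 <- 0.5 * sum((W + t(W))^2)
    S2 <- sum((rowSums(W) + colSums(W))^2)
    b2 <- n * sum(z^4) / m2^2
    varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
        ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
    zScore <- (I - EI) / sqrt(varI)
    p <- 2 * stats::pnorm(-abs(zScore))
    perms <- numeric(0)
    if (nperm > 0) {
        perms <- vapply(seq_len(nperm), function(b) {
            zp <- z[sample.int(n)]
            (n / S0) * drop(zp %*% W %*% zp) / sum(zp^2)
        }, numeric(1))
    }
    new("MoranResult", I = I, expected = EI, variance = varI, z = zScore,
        p = p, scheme = scheme, permutations = perms)
}
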