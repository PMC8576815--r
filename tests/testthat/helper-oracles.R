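## Independent oracles: deliberately naive implementations (direct
## summation, exhaustive DP, Floyd-Warshall, rotation grid search) used
## only to check the package's optimized paths.

## Direct-summation weighted displacement correlation matrix.
oracleDccm <- function(coords, weights = NULL) {
    nf <- dim(coords)[1]; n <- dim(coords)[2]
    if (is.null(weights)) weights <- rep(1, nf)
    w <- weights / sum(weights)
    mu <- matrix(0, n, 3)
    for (f in seq_len(nf)) mu <- mu + w[f] * coords[f, , ]
    C <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        num <- 0; vi <- 0; vj <- 0
        for (f in seq_len(nf)) {
            di <- coords[f, i, ] - mu[i, ]
            dj <- coords[f, j, ] - mu[j, ]
            num <- num + w[f] * sum(di * dj)
            vi <- vi + w[f] * sum(di * di)
            vj <- vj + w[f] * sum(dj * dj)
        }
        C[i, j] <- num / sqrt(vi * vj)
    }
    C
}

## All-pairs shortest path distances by Floyd-Warshall.
oracleFloydWarshall <- function(n, edges) {
    dm <- matrix(Inf, n, n)
    diag(dm) <- 0
    for (k in seq_len(nrow(edges))) {
        i <- edges$i[k]; j <- edges$j[k]
        dm[i, j] <- dm[j, i] <- min(dm[i, j], edges$weight[k])
    }
    for (k in seq_len(n))
        dm <- pmin(dm, outer(dm[, k], dm[k, ], `+`))
    dm
}

## Minimum RMSD between two point sets by hierarchical search over a
## fine Euler-angle rotation grid (translation handled by centering).
oracleRmsdGrid <- function(mobile, fixed) {
    cm <- colMeans(mobile); cf <- colMeans(fixed)
    A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
    rotmat <- function(a, b, g) {
        Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                      3, 3, byrow = TRUE)
        Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)),
                     3, 3, byrow = TRUE)
        Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1),
                      3, 3, byrow = TRUE)
        Rz1 %*% Ry %*% Rz2
    }
    evalRot <- function(a, b, g) {
        R <- rotmat(a, b, g)
        sqrt(mean(rowSums((A %*% t(R) - B)^2)))
    }
    best <- c(0, 0, 0); bestVal <- Inf
    step <- pi / 15                       # 12-degree coarse grid
    grid <- list(a = seq(0, 2 * pi, by = step),
                 b = seq(0, pi, by = step),
                 g = seq(0, 2 * pi, by = step))
    for (a in grid$a) for (b in grid$b) for (g in grid$g) {
        v <- evalRot(a, b, g)
        if (v < bestVal) { bestVal <- v; best <- c(a, b, g) }
    }
    for (refineStep in c(pi / 90, pi / 900, pi / 9000)) {
        rng <- function(c0) seq(c0 - 10 * refineStep, c0 + 10 * refineStep,
                                by = refineStep)
        for (a in rng(best[1])) for (b in rng(best[2]))
            for (g in rng(best[3])) {
                v <- evalRot(a, b, g)
                if (v < bestVal) { bestVal <- v; best <- c(a, b, g) }
            }
    }
    bestVal
}

## Global affine-gap alignment score by full Gotoh dynamic programming;
## a gap of length L costs open + L * ext (Biostrings convention).
oracleAffineScore <- function(s1, s2, open = 10, ext = 0.5) {
    sub <- .blosum62
    a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
    n <- length(a); m <- length(b)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)   # gap in s2 (consume s1)
    Y <- matrix(NEG, n + 1, m + 1)   # gap in s1 (consume s2)
    M[1, 1] <- 0
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
    for (i in seq_len(n)) for (j in seq_len(m)) {
        M[i + 1, j + 1] <- sub[a[i], b[j]] +
            max(M[i, j], X[i, j], Y[i, j])
        X[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                               X[i, j + 1] - ext)
        Y[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                               Y[i + 1, j] - ext)
    }
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

.blosum62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
})

## Direct recomputation of a weighted FEL grid from samples and edges.
oracleFel <- function(s, z, weights, kT, sBreaks, zBreaks) {
    ns <- length(sBreaks) - 1L; nz <- length(zBreaks) - 1L
    h <- matrix(0, ns, nz)
    for (k in seq_along(s)) {
        bi <- max(1L, min(ns, findInterval(s[k], sBreaks,
                                           rightmost.closed = TRUE)))
        bj <- max(1L, min(nz, findInterval(z[k], zBreaks,
                                           rightmost.closed = TRUE)))
        h[bi, bj] <- h[bi, bj] + weights[k]
    }
    p <- h / sum(h)
    fe <- matrix(NA_real_, ns, nz)
    fe[p > 0] <- -kT * log(p[p > 0])
    fe - min(fe, na.rm = TRUE)
}
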