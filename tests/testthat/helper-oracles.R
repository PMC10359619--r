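# Independent brute-force oracles. These deliberately mirror the defining
# formulas with naive loops, never the package's vectorized code paths.

# topological overlap by triple loop over the elementwise definition
bruteTOM <- function(adj) {
    n <- nrow(adj)
    k <- numeric(n)
    for (i in seq_len(n))
        k[i] <- sum(adj[i, -i])
    tom <- diag(n)
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i == j) next
            L <- 0
            for (u in seq_len(n))
                if (u != i && u != j) L <- L + adj[i, u] * adj[u, j]
            tom[i, j] <- (L + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
        }
    }
    tom
}

# random symmetric adjacency with unit diagonal
randomAdjacency <- function(n) {
    a <- matrix(stats::runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    a
}

# step-by-step average-linkage agglomeration; returns sorted merge heights
naiveAverageLinkHeights <- function(diss) {
    clusters <- as.list(seq_len(nrow(diss)))
    heights <- numeric(0)
    while (length(clusters) > 1L) {
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_along(clusters)) {
            for (j in seq_len(i - 1L)) {
                d <- mean(diss[clusters[[i]], clusters[[j]]])
                if (d < bestD) { bestD <- d; best <- c(i, j) }
            }
        }
        heights <- c(heights, bestD)
        merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
        clusters <- clusters[-best]
        clusters[[length(clusters) + 1L]] <- merged
    }
    sort(heights)
}

# upper hypergeometric tail by explicit summation of point probabilities
hyperTailOracle <- function(k, sizeA, sizeB, N) {
    hi <- min(sizeA, sizeB)
    lo <- max(0L, sizeA + sizeB - N)
    if (k > hi) return(0)
    i <- max(k, lo):hi
    sum(exp(lchoose(sizeA, i) + lchoose(N - sizeA, sizeB - i) -
            lchoose(N, sizeB)))
}

# adjusted Rand index by exhaustive pair enumeration
pairCountARI <- function(a, b) {
    n <- length(a)
    n11 <- n10 <- n01 <- n00 <- 0
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            sa <- a[i] == a[j]; sb <- b[i] == b[j]
            if (sa && sb) n11 <- n11 + 1
            else if (sa) n10 <- n10 + 1
            else if (sb) n01 <- n01 + 1
            else n00 <- n00 + 1
        }
    }
    num <- 2 * (n11 * n00 - n10 * n01)
    den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
    if (den == 0) 1 else num / den
}

# leading principal component of a standardized submatrix via a dense
# eigendecomposition of the feature covariance
eigenOracle <- function(x) {
    z <- scale(x)
    ev <- eigen(stats::cov(z), symmetric = TRUE)
    scores <- z %*% ev$vectors[, 1L]
    list(eigengene = as.numeric(scale(scores)),
         varianceExplained = ev$values[1L] / sum(ev$values))
}

# two-sided t-test p-value for a correlation via numeric integration of the
# t density (independent of stats::pt)
tTestPOracle <- function(r, n) {
    tstat <- abs(r) * sqrt((n - 2) / (1 - r^2))
    df <- n - 2
    dens <- function(x)
        gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
            (1 + x^2 / df)^(-(df + 1) / 2)
    2 * stats::integrate(dens, tstat, Inf, rel.tol = 1e-10)$value
}
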