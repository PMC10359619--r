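#' Soft-thresholded adjacency from a correlation matrix
#'
#' Transforms correlations \eqn{r} into edge weights with the soft power
#' \eqn{\beta}: unsigned \eqn{|r|^\beta}; signed
#' \eqn{((1+r)/2)^\beta}; signed-hybrid \eqn{r^\beta} for \eqn{r > 0} and 0
#' otherwise. The diagonal is set to 1.
#'
#' @param corr symmetric correlation matrix in \eqn{[-1, 1]}.
#' @param power soft-thresholding power \eqn{\beta > 0}.
#' @param networkType \code{"signed"} (default), \code{"unsigned"} or
#'   \code{"signed-hybrid"}.
#' @return adjacency matrix in \eqn{[0, 1]} with unit diagonal.
#' @examples
#' adjacencyFromCorrelation(matrix(c(1, .5, .5, 1), 2), power = 6,
#'                          networkType = "unsigned")
#' @export
adjacencyFromCorrelation <- function(corr, power = 6,
                                     networkType = c("signed", "unsigned",
                                                     "signed-hybrid")) {
    networkType <- match.arg(networkType)
    if (!is.numeric(power) || length(power) != 1L || power <= 0)
        stop("power must be a single positive number")
    .assertCorrelation(corr)
    a <- switch(networkType,
        unsigned = abs(corr)^power,
        signed = ((1 + corr) / 2)^power,
        `signed-hybrid` = ifelse(corr > 0, corr^power, 0))
    diag(a) <- 1
    a
}

.assertCorrelation <- function(corr, tol = 1e-10) {
    if (!is.matrix(corr) || nrow(corr) != ncol(corr))
        stop("correlation must be a square matrix")
    if (max(abs(corr - t(corr))) > tol)
        stop("correlation matrix must be symmetric")
    if (any(corr < -1 - tol) || any(corr > 1 + tol))
        stop("correlation entries must lie in [-1, 1]")
    invisible(TRUE)
}

.assertAdjacency <- function(adj, tol = 1e-10) {
    if (!is.matrix(adj) || nrow(adj) != ncol(adj))
        stop("adjacency must be a square matrix")
    if (max(abs(adj - t(adj))) > tol)
        stop("adjacency matrix must be symmetric")
    if (any(adj < -tol) || any(adj > 1 + tol))
        stop("adjacency entries must lie in [0, 1]")
    if (max(abs(diag(adj) - 1)) > tol)
        stop("adjacency diagonal must equal 1")
    invisible(TRUE)
}

#' Topological overlap matrix
#'
#' Computes the topological overlap \eqn{TOM_{ij} = (L_{ij} + a_{ij}) /
#' (\min(k_i, k_j) + 1 - a_{ij})} where \eqn{L_{ij} = \sum_{u \ne i,j}
#' a_{iu} a_{uj}} counts shared-neighbor weight and \eqn{k_i = \sum_{u \ne
#' i} a_{iu}} is the connectivity. The diagonal is 1. Implemented as a
#' single matrix product; equivalent to the elementwise definition to
#' machine precision.
#'
#' All adjacency types in this package yield non-negative edge weights, so
#' the signed and unsigned TOM variants coincide numerically; \code{tomType}
#' is recorded on the result for provenance.
#'
#' @param adj symmetric adjacency in \eqn{[0, 1]} with unit diagonal.
#' @param tomType \code{"signed"} (default) or \code{"unsigned"}.
#' @return TOM matrix in \eqn{[0, 1]}, unit diagonal, attribute
#'   \code{tomType}.
#' @export
tomSimilarity <- function(adj, tomType = c("signed", "unsigned")) {
    tomType <- match.arg(tomType)
    .assertAdjacency(adj)
    adj <- (adj + t(adj)) / 2   # exact symmetry for downstream hclust
    n <- nrow(adj)
    k <- rowSums(adj) - 1
    # (A^2)_ij includes u = i and u = j terms, each equal to a_ij (diag = 1)
    L <- adj %*% adj - 2 * adj
    denom <- outer(k, k, pmin) + 1 - adj
    tom <- (L + adj) / denom
    diag(tom) <- 1
    tom <- (tom + t(tom)) / 2
    attr(tom, "tomType") <- tomType
    tom
}

#' Dissimilarity from topological overlap
#'
#' @param tom TOM matrix from \code{\link{tomSimilarity}}.
#' @return \code{1 - tom}, with an exactly zero diagonal.
#' @export
tomDissimilarity <- function(tom) {
    d <- 1 - tom
    diag(d) <- 0
    attr(d, "tomType") <- NULL
    d
}

#' Pick the soft-thresholding power by scale-free fit
#'
#' For each candidate power, builds the adjacency, computes connectivities
#' \eqn{k_i}, bins \eqn{k} into equal-occupancy bins, and regresses
#' \eqn{\log_{10}} frequency on \eqn{\log_{10}} mean \eqn{k} per bin. The
#' signed scale-free fit index is \eqn{R^2 \times \mathrm{sign}(slope)}: a
#' value near 1 with negative slope indicates approximate scale-free
#' topology. The chosen power is the smallest candidate whose signed
#' \eqn{R^2} reaches \code{fitCutoff}; if none does, the candidate
#' maximizing the index is chosen with a warning.
#'
#' @param ds a \linkS4class{CoexDataSet}.
#' @param powers candidate powers, all positive. Default 1--10 and the even
#'   values 12--20.
#' @param networkType adjacency type, see
#'   \code{\link{adjacencyFromCorrelation}}.
#' @param corMethod correlation method, see
#'   \code{\link{pairwiseCorrelation}}.
#' @param fitCutoff signed R-squared threshold, default 0.9.
#' @param nBins number of equal-occupancy connectivity bins, default 10.
#' @return a \linkS4class{SoftThresholdReport}.
#' @export
pickSoftThreshold <- function(ds, powers = c(1:10, seq(12L, 20L, 2L)),
                              networkType = c("signed", "unsigned",
                                              "signed-hybrid"),
                              corMethod = c("pearson", "bicor"),
                              fitCutoff = 0.9, nBins = 10L) {
    networkType <- match.arg(networkType)
    corMethod <- match.arg(corMethod)
    if (!length(powers) || any(powers <= 0))
        stop("powers must be a non-empty vector of positive values")
    corr <- pairwiseCorrelation(ds, method = corMethod)
    rows <- lapply(powers, function(beta) {
        a <- adjacencyFromCorrelation(corr, beta, networkType)
        k <- rowSums(a) - 1
        data.frame(power = beta,
                   scaleFreeR2 = .scaleFreeFit(k, nBins),
                   meanConnectivity = mean(k),
                   medianConnectivity = stats::median(k),
                   maxConnectivity = max(k))
    })
    fit <- do.call(rbind, rows)
    ok <- which(fit$scaleFreeR2 >= fitCutoff)
    if (length(ok)) {
        chosen <- fit$power[min(ok)]
        met <- TRUE
    } else {
        chosen <- fit$power[which.max(fit$scaleFreeR2)]
        met <- FALSE
        warning("no candidate power reached the scale-free fit cutoff ",
                fitCutoff, "; using power ", chosen,
                " with the best signed R2 of ",
                signif(max(fit$scaleFreeR2), 3))
    }
    new("SoftThresholdReport", fitTable = fit, chosenPower = chosen,
        fitCutoff = fitCutoff, cutoffMet = met)
}

# signed R^2 of log10(frequency) ~ log10(mean k) over equal-occupancy bins
.scaleFreeFit <- function(k, nBins = 10L) {
    if (diff(range(k)) == 0)
        stop("degenerate connectivity: all features have identical k; ",
             "scale-free binning is undefined")
    breaks <- unique(stats::quantile(k, probs = seq(0, 1, length.out = nBins + 1L)))
    if (length(breaks) < 3L)
        stop("degenerate connectivity: too few distinct values to bin")
    bins <- cut(k, breaks = breaks, include.lowest = TRUE)
    freq <- tabulate(bins, nbins = nlevels(bins))
    meanK <- vapply(split(k, bins), function(v)
        if (length(v)) mean(v) else NA_real_, numeric(1))
    keep <- freq > 0 & !is.na(meanK) & meanK > 0
    x <- log10(meanK[keep])
    y <- log10(freq[keep])
    if (length(x) < 3L || diff(range(x)) == 0) return(0)
    f <- stats::lm(y ~ x)
    # summary.lm warns on numerically perfect fits; the R2 is still valid
    r2 <- suppressWarnings(summary(f)$r.squared)
    r2 * sign(stats::coef(f)[["x"]])
}

#' Build the full co-expression network
#'
#' Convenience wrapper running correlation, soft-power adjacency and TOM in
#' one call, returning them bundled with their parameters.
#'
#' @inheritParams pickSoftThreshold
#' @param power soft power; \code{NULL} (default) selects it with
#'   \code{\link{pickSoftThreshold}}.
#' @param tomType recorded TOM variant, see \code{\link{tomSimilarity}}.
#' @param fitCutoff scale-free fit threshold used when \code{power} is
#'   selected automatically.
#' @return a \linkS4class{CoexNetwork}.
#' @examples
#' ds <- exampleDataSet()
#' net <- buildNetwork(ds, power = 6)
#' net
#' @export
buildNetwork <- function(ds, power = NULL,
                         networkType = c("signed", "unsigned",
                                         "signed-hybrid"),
                         corMethod = c("pearson", "bicor"),
                         tomType = c("signed", "unsigned"),
                         powers = c(1:10, seq(12L, 20L, 2L)),
                         fitCutoff = 0.9) {
    networkType <- match.arg(networkType)
    corMethod <- match.arg(corMethod)
    tomType <- match.arg(tomType)
    if (is.null(power)) {
        rep_ <- pickSoftThreshold(ds, powers = powers,
                                  networkType = networkType,
                                  corMethod = corMethod,
                                  fitCutoff = fitCutoff)
        power <- rep_@chosenPower
    }
    corr <- pairwiseCorrelation(ds, method = corMethod)
    adj <- adjacencyFromCorrelation(corr, power, networkType)
    tom <- tomSimilarity(adj, tomType)
    attr(tom, "tomType") <- NULL
    net <- new("CoexNetwork", correlation = corr, adjacency = adj, tom = tom,
               power = power, networkType = networkType, tomType = tomType,
               corMethod = corMethod)
    validObject(net)
    net
}
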