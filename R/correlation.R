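#' Pairwise feature-feature correlation
#'
#' Computes the symmetric correlation matrix between all feature pairs,
#' either Pearson or biweight midcorrelation (bicor). Bicor is a robust
#' alternative that downweights outlying samples using Tukey biweights
#' around the median; features whose median absolute deviation is zero fall
#' back to Pearson for their pairs, with a warning.
#'
#' Missing values are rejected: resolve them with \code{\link{filterFeatures}}
#' first. Zero-variance features are an error because their correlation is
#' undefined.
#'
#' @param ds a \linkS4class{CoexDataSet} with at least 3 samples.
#' @param method \code{"pearson"} (default) or \code{"bicor"}.
#' @return symmetric features-by-features matrix with unit diagonal, entries
#'   in \eqn{[-1, 1]}.
#' @examples
#' ds <- exampleDataSet()
#' cc <- pairwiseCorrelation(ds)
#' range(cc)
#' @export
pairwiseCorrelation <- function(ds, method = c("pearson", "bicor")) {
    method <- match.arg(method)
    m <- exprMatrix(ds)
    if (nrow(m) < 3L)
        stop("correlation needs at least 3 samples (have ", nrow(m), ")")
    if (anyNA(m))
        stop("missing values present; resolve them before network construction")
    v <- apply(m, 2L, stats::var)
    if (any(v == 0))
        stop("zero-variance feature(s): ",
             paste(utils::head(colnames(m)[v == 0], 5L), collapse = ", "))
    r <- if (method == "pearson") stats::cor(m) else .bicor(m)
    # guard against fp excursions slightly outside [-1, 1]
    r[r > 1] <- 1
    r[r < -1] <- -1
    diag(r) <- 1
    r
}

# biweight midcorrelation, columns of m are features
.bicor <- function(m) {
    med <- apply(m, 2L, stats::median)
    ctr <- sweep(m, 2L, med)
    madRaw <- apply(abs(ctr), 2L, stats::median)
    degenerate <- madRaw == 0
    u <- sweep(ctr, 2L, ifelse(degenerate, 1, 9 * madRaw), "/")
    w <- (1 - u^2)^2 * (abs(u) < 1)
    x <- ctr * w
    norms <- sqrt(colSums(x^2))
    if (any(degenerate)) {
        warning("features with zero median absolute deviation use Pearson ",
                "fallback: ",
                paste(utils::head(colnames(m)[degenerate], 5L), collapse = ", "))
        z <- scale(m[, degenerate, drop = FALSE])
        x[, degenerate] <- z
        norms[degenerate] <- sqrt(colSums(z^2))
    }
    xn <- sweep(x, 2L, norms, "/")
    crossprod(xn)
}
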