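#' Filter low-expression and sparse features
#'
#' Removes features whose total expression across samples (missing values
#' ignored) falls below \code{minTotalExpression}, or whose fraction of
#' sparse entries -- values that are missing or \eqn{\le 0} -- exceeds
#' \code{maxMissingFraction}. Both rules are applied to the input dataset,
#' so a feature can be counted once under each rule it violates; the
#' low-expression count in the report covers features removed by that rule
#' alone.
#'
#' @param ds a \linkS4class{CoexDataSet}.
#' @param minTotalExpression features with summed expression below this are
#'   removed. Default 1.
#' @param maxMissingFraction features with a sparse-entry fraction strictly
#'   greater than this are removed. Default 0.5.
#' @return list with elements \code{dataset} (filtered
#'   \linkS4class{CoexDataSet}) and \code{report} (\linkS4class{QCReport}).
#' @examples
#' ds <- exampleDataSet()
#' res <- filterFeatures(ds, minTotalExpression = 0, maxMissingFraction = 1)
#' res$report
#' @export
filterFeatures <- function(ds, minTotalExpression = 1,
                           maxMissingFraction = 0.5) {
    if (!is.numeric(minTotalExpression) || is.na(minTotalExpression))
        stop("minTotalExpression must be numeric")
    if (!is.numeric(maxMissingFraction) || is.na(maxMissingFraction) ||
        maxMissingFraction < 0 || maxMissingFraction > 1)
        stop("maxMissingFraction must lie in [0, 1]")
    m <- exprMatrix(ds)
    totals <- colSums(m, na.rm = TRUE)
    sparseFrac <- colMeans(is.na(m) | (!is.na(m) & m <= 0))
    lowExpr <- totals < minTotalExpression
    sparse <- sparseFrac > maxMissingFraction
    drop <- lowExpr | sparse
    if (all(drop))
        stop("all features removed; relax minTotalExpression (",
             minTotalExpression, ") or maxMissingFraction (",
             maxMissingFraction, ")")
    report <- new("QCReport",
        nFeaturesRemovedLowExpression = sum(lowExpr & !sparse),
        nFeaturesRemovedSparse = sum(sparse),
        removedSampleIds = character(),
        thresholds = list(minTotalExpression = minTotalExpression,
                          maxMissingFraction = maxMissingFraction))
    list(dataset = ds[!drop, ], report = report)
}

#' Remove outlier samples by hierarchical clustering
#'
#' Clusters samples by Euclidean distance on their expression rows with
#' average linkage, cuts the tree at \code{cutHeight}, and keeps only the
#' largest resulting cluster. A cut above the dendrogram root keeps every
#' sample. A tie for the largest cluster is an error: pick a different
#' \code{cutHeight} rather than let the package discard samples arbitrarily.
#'
#' @param ds a \linkS4class{CoexDataSet} with at least 3 samples and no
#'   missing values.
#' @param cutHeight positive cut height on the sample dendrogram.
#' @return list with elements \code{dataset} and \code{report}
#'   (\linkS4class{QCReport} listing the removed sample identifiers).
#' @export
detectOutlierSamples <- function(ds, cutHeight) {
    if (!is.numeric(cutHeight) || length(cutHeight) != 1L || cutHeight <= 0)
        stop("cutHeight must be a single positive number")
    if (ncol(ds) < 3L)
        stop("outlier detection needs at least 3 samples (have ", ncol(ds), ")")
    m <- exprMatrix(ds)
    if (anyNA(m))
        stop("missing values present; run filterFeatures first")
    hc <- stats::hclust(stats::dist(m), method = "average")
    cl <- .cutAtHeight(hc, cutHeight)
    sizes <- table(cl)
    big <- names(sizes)[sizes == max(sizes)]
    if (length(big) > 1L)
        stop("tie between largest sample clusters at cutHeight = ", cutHeight,
             "; choose a different cutHeight")
    keep <- names(cl)[cl == big]
    removed <- setdiff(colnames(ds), keep)
    report <- new("QCReport",
        nFeaturesRemovedLowExpression = 0L,
        nFeaturesRemovedSparse = 0L,
        removedSampleIds = removed,
        thresholds = list(sampleCutHeight = cutHeight))
    list(dataset = ds[, keep], report = report)
}
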