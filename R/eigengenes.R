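#' Module eigengenes
#'
#' For each module, standardizes its features (zero mean, unit variance per
#' feature across samples) and extracts the first principal component of the
#' samples-by-features submatrix. Each eigengene is scaled to zero mean and
#' unit variance across samples and sign-oriented so that it correlates
#' non-negatively with the module's mean standardized expression.
#' \code{varianceExplained} is the leading eigenvalue's share of the total;
#' trailing singular values below \code{1e-12} of the leading one are
#' treated as numerically zero, so a module of identical profiles reports
#' exactly 1.
#'
#' @param ds a \linkS4class{CoexDataSet} with at least 2 samples and no
#'   missing values.
#' @param modules a \linkS4class{ModuleSet} over the dataset's features.
#' @param includeUnassigned also compute an eigengene for the unassigned
#'   label 0 when present (default \code{FALSE}).
#' @return an \linkS4class{EigengeneSet} (modules x samples).
#' @examples
#' sim <- simulateExpression(simulationDesign(30, c(20, 20), seed = 1))
#' ms <- trueModuleSet(sim)
#' eg <- computeEigengenes(sim$dataset, ms)
#' varianceExplained(eg)
#' @export
computeEigengenes <- function(ds, modules, includeUnassigned = FALSE) {
    m <- exprMatrix(ds)
    if (nrow(m) < 2L)
        stop("eigengenes need at least 2 samples")
    if (anyNA(m))
        stop("missing values present; resolve them first")
    labels <- moduleLabels(modules)
    if (!all(names(labels) %in% colnames(m)))
        stop("module features missing from the dataset: ",
             paste(utils::head(setdiff(names(labels), colnames(m)), 5L),
                   collapse = ", "))
    mods <- sort(unique(labels[labels > 0L]))
    if (includeUnassigned && any(labels == 0L)) mods <- c(0L, mods)
    if (!length(mods))
        stop("no modules to summarize (all features unassigned)")
    nS <- nrow(m)
    eg <- matrix(NA_real_, length(mods), nS,
                 dimnames = list(as.character(mods), rownames(m)))
    ve <- stats::setNames(numeric(length(mods)), as.character(mods))
    sg <- stats::setNames(numeric(length(mods)), as.character(mods))
    for (i in seq_along(mods)) {
        feats <- names(labels)[labels == mods[i]]
        if (!length(feats))
            stop("module ", mods[i], " has no features")
        sub <- m[, feats, drop = FALSE]
        sds <- apply(sub, 2L, stats::sd)
        if (any(sds == 0))
            stop("constant feature(s) in module ", mods[i], ": ",
                 paste(utils::head(feats[sds == 0], 3L), collapse = ", "))
        z <- scale(sub)
        sv <- svd(z, nu = 1L, nv = 0L)
        d2 <- sv$d^2
        d2[sv$d < 1e-12 * sv$d[1L]] <- 0
        ve[i] <- d2[1L] / sum(d2)
        e <- sv$u[, 1L]
        s <- if (stats::sd(e) > 0) sum(e * rowMeans(z)) else 1
        sgn <- if (s < 0) -1 else 1
        e <- e * sgn
        e <- e - mean(e)
        e <- e / stats::sd(e)
        eg[i, ] <- e
        sg[i] <- sgn
    }
    out <- new("EigengeneSet", eigengenes = eg, varianceExplained = ve,
               orientationSign = sg)
    validObject(out)
    out
}

#' Merge modules with highly correlated eigengenes
#'
#' Clusters module eigengenes by \eqn{1 - } correlation (average linkage)
#' and merges every group of modules joined below \code{mergeCutHeight};
#' eigengenes are recomputed after each merge round and merging repeats
#' until stable. \code{mergeCutHeight = 0.25} merges modules whose
#' eigengenes correlate above 0.75; \code{0} never merges.
#'
#' @param ds a \linkS4class{CoexDataSet}.
#' @param modules a \linkS4class{ModuleSet}.
#' @param mergeCutHeight eigengene-dissimilarity threshold in \eqn{[0, 1]}.
#' @return list with elements \code{modules} (merged
#'   \linkS4class{ModuleSet}, labels reordered by size) and
#'   \code{eigengenes} (recomputed \linkS4class{EigengeneSet}).
#' @export
mergeCloseModules <- function(ds, modules, mergeCutHeight = 0.25) {
    if (mergeCutHeight < 0 || mergeCutHeight > 1)
        stop("mergeCutHeight must lie in [0, 1]")
    labels <- moduleLabels(modules)
    repeat {
        mods <- sort(unique(labels[labels > 0L]))
        if (length(mods) < 2L || mergeCutHeight == 0) break
        ms <- .newModuleSet(labels, modules@dendrogram, modules@params)
        eg <- computeEigengenes(ds, ms)
        ce <- stats::cor(t(eigengenes(eg)))
        dis <- 1 - ce
        hc <- stats::hclust(stats::as.dist(dis), method = "average")
        grp <- .cutAtHeight(hc, mergeCutHeight)
        if (max(table(grp)) == 1L) break
        # merge each group into its largest member's label
        sizes <- table(labels[labels > 0L])
        newLab <- labels
        for (g in unique(grp)) {
            members <- as.integer(names(grp)[grp == g])
            if (length(members) < 2L) next
            target <- members[which.max(sizes[as.character(members)])]
            newLab[labels %in% members] <- target
        }
        labels <- newLab
    }
    labels <- .relabelBySize(labels)
    ms <- .newModuleSet(labels, modules@dendrogram,
                        c(modules@params, list(mergeCutHeight = mergeCutHeight)))
    list(modules = ms, eigengenes = computeEigengenes(ds, ms))
}
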