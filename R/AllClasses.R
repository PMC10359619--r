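#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData assayNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CoexDataSet: expression matrix with sample and feature annotations
#'
#' Container for a numeric expression matrix together with per-sample and
#' per-feature metadata, aligned by identifier. It extends
#' \linkS4class{SummarizedExperiment}, so the assay is stored in the
#' Bioconductor convention of features in rows and samples in columns;
#' \code{\link{exprMatrix}} returns the samples-by-features view that the
#' network computations consume. Sample metadata live in \code{colData},
#' feature metadata in \code{rowData}.
#'
#' Identifiers must be unique and non-empty on both axes. Missing values are
#' permitted at ingestion but must be removed (see
#' \code{\link{filterFeatures}}) before network construction; the correlation
#' step refuses missing data rather than silently pairwise-deleting.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso \code{\link{readExpression}}, \code{\link{attachMetadata}}
#' @export
setClass("CoexDataSet", contains = "SummarizedExperiment")

setValidity("CoexDataSet", function(object) {
    msg <- character()
    if (length(assays(object)) < 1L)
        return("CoexDataSet must carry one assay")
    m <- assay(object)
    if (!is.numeric(m))
        msg <- c(msg, "expression assay must be numeric")
    fid <- rownames(object)
    sid <- colnames(object)
    if (is.null(fid) || anyNA(fid) || any(fid == ""))
        msg <- c(msg, "feature identifiers must be non-empty")
    if (is.null(sid) || anyNA(sid) || any(sid == ""))
        msg <- c(msg, "sample identifiers must be non-empty")
    if (!is.null(fid) && anyDuplicated(fid))
        msg <- c(msg, sprintf("duplicated feature identifiers: %s",
                              paste(unique(fid[duplicated(fid)]), collapse = ", ")))
    if (!is.null(sid) && anyDuplicated(sid))
        msg <- c(msg, sprintf("duplicated sample identifiers: %s",
                              paste(unique(sid[duplicated(sid)]), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' CoexNetwork: correlation, adjacency and topological overlap matrices
#'
#' Holds the three symmetric feature-by-feature matrices of a weighted
#' co-expression network -- correlation, soft-thresholded adjacency and the
#' topological overlap matrix (TOM) -- together with the parameters that
#' produced them.
#'
#' @slot correlation symmetric matrix of pairwise feature correlations in
#'   \eqn{[-1, 1]} with unit diagonal.
#' @slot adjacency symmetric matrix in \eqn{[0, 1]} with unit diagonal.
#' @slot tom symmetric topological overlap matrix in \eqn{[0, 1]} with unit
#'   diagonal.
#' @slot power soft-thresholding power \eqn{\beta > 0}.
#' @slot networkType one of \code{"signed"}, \code{"unsigned"},
#'   \code{"signed-hybrid"}.
#' @slot tomType one of \code{"signed"}, \code{"unsigned"} (recorded
#'   provenance; see \code{\link{tomSimilarity}}).
#' @slot corMethod correlation method used (\code{"pearson"} or
#'   \code{"bicor"}).
#' @seealso \code{\link{buildNetwork}}
#' @export
setClass("CoexNetwork",
    representation(
        correlation = "matrix",
        adjacency   = "matrix",
        tom         = "matrix",
        power       = "numeric",
        networkType = "character",
        tomType     = "character",
        corMethod   = "character"
    )
)

.checkSquareSym <- function(m, what, lo, hi, diagVal, tol = 1e-10) {
    msg <- character()
    if (nrow(m) != ncol(m))
        return(sprintf("%s matrix must be square", what))
    if (nrow(m) > 0L) {
        if (max(abs(m - t(m))) > tol)
            msg <- c(msg, sprintf("%s matrix must be symmetric (tol %g)", what, tol))
        if (any(m < lo - tol) || any(m > hi + tol))
            msg <- c(msg, sprintf("%s entries must lie in [%g, %g]", what, lo, hi))
        if (max(abs(diag(m) - diagVal)) > tol)
            msg <- c(msg, sprintf("%s diagonal must equal %g", what, diagVal))
    }
    msg
}

setValidity("CoexNetwork", function(object) {
    msg <- character()
    msg <- c(msg, .checkSquareSym(object@correlation, "correlation", -1, 1, 1))
    msg <- c(msg, .checkSquareSym(object@adjacency, "adjacency", 0, 1, 1))
    msg <- c(msg, .checkSquareSym(object@tom, "TOM", 0, 1, 1))
    if (length(object@power) != 1L || object@power <= 0)
        msg <- c(msg, "power must be a single positive number")
    if (!object@networkType %in% c("signed", "unsigned", "signed-hybrid"))
        msg <- c(msg, "networkType must be signed, unsigned or signed-hybrid")
    if (!object@tomType %in% c("signed", "unsigned"))
        msg <- c(msg, "tomType must be signed or unsigned")
    dims <- c(nrow(object@correlation), nrow(object@adjacency), nrow(object@tom))
    if (length(unique(dims)) != 1L)
        msg <- c(msg, "correlation, adjacency and TOM must share dimensions")
    if (length(msg)) msg else TRUE
})

#' ModuleSet: feature-to-module assignment with dendrogram provenance
#'
#' Assignment of every feature to a module label. Label \code{0} (color
#' \code{"grey"}) marks unassigned features; labels \code{1..M} are ordered
#' by decreasing module size. The feature dendrogram the assignment was cut
#' from is retained.
#'
#' @slot labels named integer vector, one entry per feature; names are
#'   feature identifiers.
#' @slot colors named character vector mapping module labels (as character)
#'   to conventional color names; label \code{"0"} maps to \code{"grey"}.
#' @slot dendrogram the \code{\link[stats]{hclust}} feature tree, or
#'   \code{NULL} when the assignment was loaded from a table.
#' @slot params named list of the cut parameters used.
#' @seealso \code{\link{cutModules}}, \code{\link{moduleColors}}
#' @export
setClass("ModuleSet",
    representation(
        labels     = "integer",
        colors     = "character",
        dendrogram = "ANY",
        params     = "list"
    )
)

setValidity("ModuleSet", function(object) {
    msg <- character()
    if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
        msg <- c(msg, "labels must be named by unique feature identifiers")
    if (length(object@labels) && any(object@labels < 0L))
        msg <- c(msg, "module labels must be >= 0")
    lab <- sort(unique(object@labels))
    if (!all(as.character(lab) %in% names(object@colors)))
        msg <- c(msg, "every module label needs a color entry")
    if ("0" %in% names(object@colors) && object@colors[["0"]] != "grey")
        msg <- c(msg, "label 0 must map to color 'grey'")
    if (!is.null(object@dendrogram) && !inherits(object@dendrogram, "hclust"))
        msg <- c(msg, "dendrogram must be an hclust object or NULL")
    if (length(msg)) msg else TRUE
})

#' EigengeneSet: per-module first-principal-component summaries
#'
#' One eigengene per module: the first principal component of the module's
#' standardized expression submatrix, scaled to zero mean and unit variance
#' across samples and sign-oriented so it correlates non-negatively with the
#' module's mean standardized expression.
#'
#' @slot eigengenes modules-by-samples numeric matrix; row names are module
#'   labels (as character), column names are sample identifiers.
#' @slot varianceExplained named numeric in \eqn{[0, 1]}, fraction of module
#'   variance captured by the eigengene.
#' @slot orientationSign named numeric, \code{+1} or \code{-1}, the sign flip
#'   applied to enforce the orientation convention.
#' @seealso \code{\link{computeEigengenes}}
#' @export
setClass("EigengeneSet",
    representation(
        eigengenes        = "matrix",
        varianceExplained = "numeric",
        orientationSign   = "numeric"
    )
)

setValidity("EigengeneSet", function(object) {
    msg <- character()
    e <- object@eigengenes
    if (nrow(e)) {
        if (is.null(rownames(e)) || is.null(colnames(e)))
            msg <- c(msg, "eigengene matrix must have module and sample names")
        mu <- rowMeans(e)
        if (max(abs(mu)) > 1e-8)
            msg <- c(msg, "eigengenes must have zero mean across samples")
        if (ncol(e) > 1L) {
            v <- apply(e, 1L, stats::var)
            if (max(abs(v - 1)) > 1e-8)
                msg <- c(msg, "eigengenes must have unit variance across samples")
        }
        ve <- object@varianceExplained
        if (length(ve) != nrow(e))
            msg <- c(msg, "varianceExplained must have one entry per module")
        if (any(ve < 0 | ve > 1))
            msg <- c(msg, "varianceExplained must lie in [0, 1]")
        if (!all(object@orientationSign %in% c(-1, 1)))
            msg <- c(msg, "orientationSign entries must be -1 or +1")
    }
    if (length(msg)) msg else TRUE
})

#' QCReport: record of preprocessing removals
#'
#' @slot nFeaturesRemovedLowExpression count removed by the total-expression
#'   rule.
#' @slot nFeaturesRemovedSparse count removed by the sparsity rule.
#' @slot removedSampleIds identifiers of samples removed as outliers.
#' @slot thresholds named list of the thresholds applied.
#' @seealso \code{\link{filterFeatures}}, \code{\link{detectOutlierSamples}}
#' @export
setClass("QCReport",
    representation(
        nFeaturesRemovedLowExpression = "integer",
        nFeaturesRemovedSparse        = "integer",
        removedSampleIds              = "character",
        thresholds                    = "list"
    ),
    prototype(
        nFeaturesRemovedLowExpression = 0L,
        nFeaturesRemovedSparse        = 0L,
        removedSampleIds              = character(),
        thresholds                    = list()
    )
)

setValidity("QCReport", function(object) {
    if (object@nFeaturesRemovedLowExpression < 0L ||
        object@nFeaturesRemovedSparse < 0L)
        "removal counts must be non-negative"
    else TRUE
})

#' SoftThresholdReport: scale-free fit across candidate powers
#'
#' @slot fitTable data.frame with one row per candidate power: \code{power},
#'   \code{scaleFreeR2} (signed R-squared of the log-log degree fit),
#'   \code{meanConnectivity}, \code{medianConnectivity},
#'   \code{maxConnectivity}.
#' @slot chosenPower the selected power.
#' @slot fitCutoff the signed R-squared threshold used for selection.
#' @slot cutoffMet whether any candidate reached the cutoff.
#' @seealso \code{\link{pickSoftThreshold}}
#' @export
setClass("SoftThresholdReport",
    representation(
        fitTable    = "data.frame",
        chosenPower = "numeric",
        fitCutoff   = "numeric",
        cutoffMet   = "logical"
    )
)

#' SimulationDesign: parameters of the planted-module generator
#'
#' @slot nSamples number of samples to draw.
#' @slot moduleSizes integer vector of features per planted module.
#' @slot nBackground number of unassigned pure-noise features.
#' @slot withinModuleCor target pairwise correlation within each module, in
#'   (0, 1); recycled across modules.
#' @slot noiseSd standard deviation of the feature-level noise.
#' @slot traitLinks data.frame with columns \code{module} (1-based index),
#'   \code{trait} (name), \code{effect} (linear effect size) and \code{type}
#'   (\code{"numeric"} or \code{"binary"}); may have zero rows.
#' @slot sharedFactorGroups optional list of integer vectors; modules in one
#'   group share a single latent factor (for testing module merging).
#' @slot seed master seed; all draws derive from it.
#' @seealso \code{\link{simulateExpression}}
#' @export
setClass("SimulationDesign",
    representation(
        nSamples           = "integer",
        moduleSizes        = "integer",
        nBackground        = "integer",
        withinModuleCor    = "numeric",
        noiseSd            = "numeric",
        traitLinks         = "data.frame",
        sharedFactorGroups = "list",
        seed               = "integer"
    )
)

setValidity("SimulationDesign", function(object) {
    msg <- character()
    if (object@nSamples < 2L)
        msg <- c(msg, "nSamples must be >= 2")
    if (length(object@moduleSizes) && any(object@moduleSizes < 1L))
        msg <- c(msg, "moduleSizes must be positive")
    if (object@nBackground < 0L)
        msg <- c(msg, "nBackground must be >= 0")
    if (length(object@moduleSizes) + object@nBackground < 1L)
        msg <- c(msg, "design must contain at least one feature")
    if (any(object@withinModuleCor <= 0 | object@withinModuleCor >= 1))
        msg <- c(msg, "withinModuleCor must lie strictly in (0, 1)")
    if (length(object@moduleSizes) &&
        !length(object@withinModuleCor) %in% c(1L, length(object@moduleSizes)))
        msg <- c(msg, "withinModuleCor must have length 1 or one per module")
    if (object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be positive")
    tl <- object@traitLinks
    if (nrow(tl)) {
        need <- c("module", "trait", "effect", "type")
        if (!all(need %in% names(tl)))
            msg <- c(msg, "traitLinks needs columns module, trait, effect, type")
        else if (any(tl$module < 1L | tl$module > length(object@moduleSizes)))
            msg <- c(msg, "traitLinks$module indices out of range")
        else if (!all(tl$type %in% c("numeric", "binary")))
            msg <- c(msg, "traitLinks$type must be 'numeric' or 'binary'")
    }
    for (g in object@sharedFactorGroups) {
        if (any(g < 1L | g > length(object@moduleSizes)))
            msg <- c(msg, "sharedFactorGroups indices out of range")
    }
    if (length(msg)) msg else TRUE
})
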