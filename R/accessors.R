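#' Expression matrix in samples-by-features orientation
#'
#' Returns the expression values of a \linkS4class{CoexDataSet} as a base
#' matrix with samples in rows and features in columns -- the orientation
#' every correlation and network computation in this package consumes.
#'
#' @param x a \linkS4class{CoexDataSet}.
#' @param ... ignored.
#' @return numeric matrix, samples x features, with identifier dimnames.
#' @examples
#' ds <- exampleDataSet()
#' dim(exprMatrix(ds))
#' @rdname exprMatrix
#' @export
setMethod("exprMatrix", "CoexDataSet", function(x, ...) {
    t(assay(x))
})

#' Sample and feature metadata
#'
#' \code{sampleData} returns the per-sample annotation (the
#' \code{colData}); \code{featureData} the per-feature annotation (the
#' \code{rowData}), each as a \code{DataFrame} keyed by identifier.
#'
#' @param x a \linkS4class{CoexDataSet}.
#' @param ... ignored.
#' @return a \code{\link[S4Vectors]{DataFrame}}.
#' @rdname sampleData
#' @export
setMethod("sampleData", "CoexDataSet", function(x, ...) colData(x))

#' @rdname sampleData
#' @export
setMethod("featureData", "CoexDataSet", function(x, ...) rowData(x))

#' Number of samples / features
#' @param ds a \linkS4class{CoexDataSet}.
#' @return integer count.
#' @rdname exprMatrix
#' @export
nSamples <- function(ds) ncol(ds)

#' @rdname exprMatrix
#' @export
nFeatures <- function(ds) nrow(ds)

setMethod("show", "CoexDataSet", function(object) {
    cat("CoexDataSet:", ncol(object), "samples x", nrow(object), "features\n")
    cat("  sample annotations:",
        paste(colnames(colData(object)), collapse = ", "), "\n")
    cat("  feature annotations:",
        paste(colnames(rowData(object)), collapse = ", "), "\n")
    nmiss <- sum(is.na(assay(object)))
    if (nmiss > 0L) cat("  missing values:", nmiss, "\n")
})

#' Module assignment accessors
#'
#' \code{moduleLabels} returns the named integer label vector (0 =
#' unassigned); \code{moduleColors} the per-feature color rendering;
#' \code{moduleSizes} the per-label feature counts; \code{moduleGenes} a
#' list of feature-identifier vectors, one per module label.
#'
#' @param x a \linkS4class{ModuleSet}.
#' @param ... ignored.
#' @rdname moduleLabels
#' @export
setMethod("moduleLabels", "ModuleSet", function(x, ...) x@labels)

#' @rdname moduleLabels
#' @export
setMethod("moduleColors", "ModuleSet", function(x, ...) {
    stats::setNames(unname(x@colors[as.character(x@labels)]), names(x@labels))
})

#' @rdname moduleLabels
#' @export
setMethod("moduleSizes", "ModuleSet", function(x, ...) {
    tab <- table(x@labels)
    stats::setNames(as.integer(tab), names(tab))
})

#' @param includeUnassigned include label 0 as a pseudo-module?
#' @rdname moduleLabels
#' @export
setMethod("moduleGenes", "ModuleSet", function(x, includeUnassigned = FALSE, ...) {
    keep <- if (includeUnassigned) x@labels >= 0L else x@labels > 0L
    split(names(x@labels)[keep], x@labels[keep])
})

setMethod("show", "ModuleSet", function(object) {
    sz <- moduleSizes(object)
    nm <- sum(names(sz) != "0")
    cat("ModuleSet:", nm, "modules over", length(object@labels), "features\n")
    unas <- if ("0" %in% names(sz)) sz[["0"]] else 0L
    cat("  unassigned (grey):", unas, "\n")
    mods <- sz[names(sz) != "0"]
    if (length(mods)) {
        cols <- object@colors[names(mods)]
        cat("  sizes:", paste(sprintf("%s=%d", cols, mods), collapse = ", "), "\n")
    }
})

#' Eigengene accessors
#'
#' @param x an \linkS4class{EigengeneSet}.
#' @param ... ignored.
#' @return \code{eigengenes}: modules x samples matrix;
#'   \code{varianceExplained}: named numeric fractions.
#' @rdname eigengenes
#' @export
setMethod("eigengenes", "EigengeneSet", function(x, ...) x@eigengenes)

#' @rdname eigengenes
#' @export
setMethod("varianceExplained", "EigengeneSet", function(x, ...)
    x@varianceExplained)

setMethod("show", "EigengeneSet", function(object) {
    cat("EigengeneSet:", nrow(object@eigengenes), "modules x",
        ncol(object@eigengenes), "samples\n")
    cat("  variance explained:",
        paste(sprintf("%s=%.2f", names(object@varianceExplained),
                      object@varianceExplained), collapse = ", "), "\n")
})

#' Network accessors
#'
#' @param x a \linkS4class{CoexNetwork}.
#' @param ... ignored.
#' @rdname networkAccessors
#' @export
setMethod("correlationMatrix", "CoexNetwork", function(x, ...) x@correlation)

#' @rdname networkAccessors
#' @export
setMethod("adjacencyMatrix", "CoexNetwork", function(x, ...) x@adjacency)

#' @rdname networkAccessors
#' @export
setMethod("tomMatrix", "CoexNetwork", function(x, ...) x@tom)

#' @rdname networkAccessors
#' @export
setMethod("softPower", "CoexNetwork", function(x, ...) x@power)

setMethod("show", "CoexNetwork", function(object) {
    cat("CoexNetwork:", nrow(object@adjacency), "features\n")
    cat(sprintf("  %s correlation, %s network, power %g, %s TOM\n",
                object@corMethod, object@networkType, object@power,
                object@tomType))
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport\n")
    cat("  features removed (low expression):",
        object@nFeaturesRemovedLowExpression, "\n")
    cat("  features removed (sparse):", object@nFeaturesRemovedSparse, "\n")
    cat("  samples removed:", length(object@removedSampleIds),
        if (length(object@removedSampleIds))
            paste0("(", paste(object@removedSampleIds, collapse = ", "), ")")
        else "", "\n")
    if (length(object@thresholds)) {
        th <- vapply(object@thresholds, function(v) paste(format(v), collapse = ","),
                     character(1))
        cat("  thresholds:", paste(names(th), th, sep = "=", collapse = ", "), "\n")
    }
})

setMethod("show", "SoftThresholdReport", function(object) {
    cat("SoftThresholdReport: chosen power", object@chosenPower,
        sprintf("(signed R2 cutoff %g%s)\n", object@fitCutoff,
                if (object@cutoffMet) "" else ", cutoff not met"))
    print(object@fitTable, row.names = FALSE, digits = 3)
})

setMethod("show", "SimulationDesign", function(object) {
    cat("SimulationDesign:", object@nSamples, "samples,",
        length(object@moduleSizes), "modules (",
        paste(object@moduleSizes, collapse = ", "), ") +",
        object@nBackground, "background features\n")
    cat("  within-module correlation:",
        paste(object@withinModuleCor, collapse = ", "),
        "; noise sd:", object@noiseSd, "; seed:", object@seed, "\n")
    if (nrow(object@traitLinks))
        cat("  trait links:", nrow(object@traitLinks), "\n")
})
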