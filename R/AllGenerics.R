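#' @rdname exprMatrix
#' @export
setGeneric("exprMatrix", function(x, ...) standardGeneric("exprMatrix"))

#' @rdname sampleData
#' @export
setGeneric("sampleData", function(x, ...) standardGeneric("sampleData"))

#' @rdname sampleData
#' @export
setGeneric("featureData", function(x, ...) standardGeneric("featureData"))

#' @rdname moduleLabels
#' @export
setGeneric("moduleLabels", function(x, ...) standardGeneric("moduleLabels"))

#' @rdname moduleLabels
#' @export
setGeneric("moduleColors", function(x, ...) standardGeneric("moduleColors"))

#' @rdname moduleLabels
#' @export
setGeneric("moduleSizes", function(x, ...) standardGeneric("moduleSizes"))

#' @rdname moduleLabels
#' @export
setGeneric("moduleGenes", function(x, ...) standardGeneric("moduleGenes"))

#' @rdname eigengenes
#' @export
setGeneric("eigengenes", function(x, ...) standardGeneric("eigengenes"))

#' @rdname eigengenes
#' @export
setGeneric("varianceExplained", function(x, ...)
    standardGeneric("varianceExplained"))

#' @rdname networkAccessors
#' @export
setGeneric("correlationMatrix", function(x, ...)
    standardGeneric("correlationMatrix"))

#' @rdname networkAccessors
#' @export
setGeneric("adjacencyMatrix", function(x, ...)
    standardGeneric("adjacencyMatrix"))

#' @rdname networkAccessors
#' @export
setGeneric("tomMatrix", function(x, ...) standardGeneric("tomMatrix"))

#' @rdname networkAccessors
#' @export
setGeneric("softPower", function(x, ...) standardGeneric("softPower"))
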