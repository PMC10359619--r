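#' One-sided Fisher enrichment p-value for set overlap
#'
#' Probability of observing an overlap at least as large as \code{nShared}
#' between a set of size \code{sizeA} and a set of size \code{sizeB} drawn
#' from a universe of \code{universeSize} genes -- the upper hypergeometric
#' tail, equivalent to a one-sided (greater) Fisher exact test on the 2x2
#' membership table.
#'
#' @param nShared observed overlap count.
#' @param sizeA,sizeB set sizes.
#' @param universeSize total genes in the universe.
#' @param alternative \code{"greater"} (enrichment, default) or
#'   \code{"two.sided"} (via \code{\link[stats]{fisher.test}}).
#' @return p-value in \eqn{[0, 1]}.
#' @export
fisherOverlapP <- function(nShared, sizeA, sizeB, universeSize,
                           alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    stopifnot(nShared >= 0, sizeA >= nShared, sizeB >= nShared,
              universeSize >= sizeA + sizeB - nShared)
    if (alternative == "greater")
        return(stats::phyper(nShared - 1, sizeA, universeSize - sizeA,
                             sizeB, lower.tail = FALSE))
    tab <- matrix(c(nShared, sizeA - nShared,
                    sizeB - nShared,
                    universeSize - sizeA - sizeB + nShared), 2L)
    stats::fisher.test(tab, alternative = "two.sided")$p.value
}

.resolveUniverse <- function(setsA, setsB, universe) {
    allGenes <- unique(c(unlist(setsA, use.names = FALSE),
                         unlist(setsB, use.names = FALSE)))
    if (is.character(universe) && length(universe) == 1L &&
        universe %in% c("union", "intersection")) {
        if (universe == "union") return(unique(allGenes))
        return(intersect(unique(unlist(setsA, use.names = FALSE)),
                         unique(unlist(setsB, use.names = FALSE))))
    }
    unique(as.character(universe))
}

#' Overlap statistics between two collections of gene sets
#'
#' For every pair of one set from \code{setsA} and one from \code{setsB},
#' computes the shared-gene count, Jaccard index \eqn{|A \cap B| / |A \cup
#' B|}, the shared fraction of each set, and a one-sided Fisher exact
#' (hypergeometric enrichment) p-value over the chosen gene universe, with
#' Benjamini-Hochberg adjustment across all pairs.
#'
#' The universe is a mandatory, consequential choice: \code{"union"}
#' (default, all genes appearing in either collection),
#' \code{"intersection"} (genes present in both collections' unions), or an
#' explicit character vector. Genes outside an explicit universe are
#' dropped from the sets with a warning; a set left disjoint from the
#' universe is an error.
#'
#' @param setsA,setsB named lists of character gene sets (e.g. from
#'   \code{\link{moduleGenes}}); names label the modules/lists.
#' @param universe \code{"union"}, \code{"intersection"}, or a character
#'   vector.
#' @param alternative Fisher sidedness, see \code{\link{fisherOverlapP}}.
#' @return data.frame with one row per pair: \code{moduleA}, \code{moduleB},
#'   \code{sizeA}, \code{sizeB}, \code{nShared}, \code{jaccard},
#'   \code{fractionOfA}, \code{fractionOfB}, \code{fisherP},
#'   \code{fisherPAdjusted}, \code{universeSize}.
#' @examples
#' compareModuleSets(list(m1 = c("g1", "g2", "g3")),
#'                   list(x = c("g2", "g3", "g4")))
#' @export
compareModuleSets <- function(setsA, setsB, universe = "union",
                              alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    if (!length(setsA) || !length(setsB))
        stop("both collections must contain at least one set")
    if (is.null(names(setsA))) names(setsA) <- paste0("A", seq_along(setsA))
    if (is.null(names(setsB))) names(setsB) <- paste0("B", seq_along(setsB))
    setsA <- lapply(setsA, function(s) unique(as.character(s)))
    setsB <- lapply(setsB, function(s) unique(as.character(s)))
    if (any(!lengths(setsA)) || any(!lengths(setsB)))
        stop("empty gene set(s): ",
             paste(c(names(setsA)[!lengths(setsA)],
                     names(setsB)[!lengths(setsB)]), collapse = ", "))
    uni <- .resolveUniverse(setsA, setsB, universe)
    if (!length(uni)) stop("empty gene universe")
    trim <- function(sets, tag) {
        out <- lapply(sets, intersect, uni)
        lost <- sum(lengths(sets)) - sum(lengths(out))
        if (lost > 0)
            warning(lost, " gene occurrence(s) outside the universe dropped ",
                    "from ", tag)
        dead <- names(out)[lengths(out) == 0L]
        if (length(dead))
            stop("set(s) disjoint from the universe: ",
                 paste(dead, collapse = ", "))
        out
    }
    setsA <- trim(setsA, "setsA")
    setsB <- trim(setsB, "setsB")
    N <- length(uni)
    grid <- expand.grid(moduleA = names(setsA), moduleB = names(setsB),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- mapply(function(a, b) {
        A <- setsA[[a]]; B <- setsB[[b]]
        sh <- length(intersect(A, B))
        un <- length(A) + length(B) - sh
        c(sizeA = length(A), sizeB = length(B), nShared = sh,
          jaccard = sh / un,
          fractionOfA = sh / length(A), fractionOfB = sh / length(B),
          fisherP = fisherOverlapP(sh, length(A), length(B), N, alternative))
    }, grid$moduleA, grid$moduleB)
    out <- data.frame(grid, t(rows))
    out$fisherPAdjusted <- stats::p.adjust(out$fisherP, method = "BH")
    out$universeSize <- N
    rownames(out) <- NULL
    out
}

#' Compare module gene sets against marker-gene lists
#'
#' Identical statistics to \code{\link{compareModuleSets}} with the second
#' collection given by named marker-gene lists (e.g. cell-type markers from
#' single-cell clustering), revealing the cell-type specificity of each
#' co-expression module.
#'
#' @param sets named list of module gene sets.
#' @param markers named list of marker gene sets.
#' @inheritParams compareModuleSets
#' @return as \code{\link{compareModuleSets}}.
#' @export
compareToMarkerLists <- function(sets, markers, universe = "union",
                                 alternative = c("greater", "two.sided")) {
    compareModuleSets(sets, markers, universe = universe,
                      alternative = match.arg(alternative))
}

#' Filter an overlap table for reporting
#'
#' Keeps pairs with Jaccard index strictly greater than \code{minJaccard}
#' and adjusted p-value at most \code{maxAdjustedP} -- the edge list of a
#' module-comparison graph in which edge weight is the Jaccard index.
#'
#' @param result data.frame from \code{\link{compareModuleSets}}.
#' @param minJaccard strict lower Jaccard bound, default 0.05.
#' @param maxAdjustedP adjusted-p ceiling, default 0.05.
#' @return the filtered data.frame.
#' @export
filterComparison <- function(result, minJaccard = 0.05, maxAdjustedP = 0.05) {
    stopifnot(minJaccard >= 0, minJaccard <= 1,
              maxAdjustedP >= 0, maxAdjustedP <= 1)
    result[result$jaccard > minJaccard &
           result$fisherPAdjusted <= maxAdjustedP, , drop = FALSE]
}
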