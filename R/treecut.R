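#' Average-linkage clustering of the network dissimilarity
#'
#' @param diss symmetric dissimilarity matrix with zero diagonal and
#'   non-negative entries (typically \code{\link{tomDissimilarity}} output).
#' @return an \code{\link[stats]{hclust}} tree over the features.
#' @export
clusterFeatures <- function(diss) {
    if (!is.matrix(diss) || nrow(diss) != ncol(diss))
        stop("dissimilarity must be a square matrix")
    if (nrow(diss) < 2L)
        stop("clustering needs at least 2 features")
    if (max(abs(diss - t(diss))) > 1e-10)
        stop("dissimilarity must be symmetric")
    if (any(diss < -1e-12))
        stop("dissimilarity must be non-negative")
    if (max(abs(diag(diss))) > 1e-12)
        stop("dissimilarity diagonal must be zero")
    stats::hclust(stats::as.dist(diss), method = "average")
}

# --- dendrogram bookkeeping -------------------------------------------------
# hclust encodes node i's children in merge[i, ]: negative = leaf index,
# positive = earlier merge. We precompute, per internal node, its leaf set
# and height.
.treeIndex <- function(hc) {
    n <- length(hc$order)
    nodes <- vector("list", n - 1L)
    for (i in seq_len(n - 1L)) {
        kids <- hc$merge[i, ]
        leaves <- integer()
        for (k in kids) {
            leaves <- c(leaves, if (k < 0) -k else nodes[[k]]$leaves)
        }
        nodes[[i]] <- list(leaves = leaves, height = hc$height[i],
                           children = kids)
    }
    nodes
}

# connected components after removing merges above height h; tolerant of the
# tied/epsilon-jittered heights that average linkage produces on block data
# (stats::cutree refuses trees whose height vector is not non-decreasing)
.cutAtHeight <- function(hc, h) {
    n <- length(hc$order)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    nodeRep <- integer(nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
        kids <- hc$merge[i, ]
        reps <- ifelse(kids < 0, -kids, nodeRep[pmax(kids, 1L)])
        nodeRep[i] <- reps[1L]
        if (hc$height[i] <= h) {
            r1 <- find(reps[1L]); r2 <- find(reps[2L])
            parent[r2] <- r1
        }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    cl <- match(comp, unique(comp))
    stats::setNames(cl, hc$labels)
}

# height of a child reference (leaf -> 0)
.childHeight <- function(nodes, k) if (k < 0) 0 else nodes[[k]]$height

.childLeaves <- function(nodes, k) if (k < 0) -k else nodes[[k]]$leaves

# mean pairwise dissimilarity among the branch "core": the nCore leaves with
# the lowest average within-branch dissimilarity
.coreScatter <- function(diss, leaves, minModuleSize) {
    nl <- length(leaves)
    if (nl < 2L) return(0)
    sub <- diss[leaves, leaves, drop = FALSE]
    avg <- rowSums(sub) / (nl - 1L)
    nCore <- min(nl, max(minModuleSize, ceiling(sqrt(nl))))
    core <- order(avg)[seq_len(nCore)]
    cs <- sub[core, core, drop = FALSE]
    sum(cs) / (nCore * (nCore - 1L))
}

#' Adaptive (dynamic) cut of the feature dendrogram into modules
#'
#' Identifies modules as dendrogram branches using an adaptive hybrid
#' procedure rather than a single fixed cut:
#' \enumerate{
#'   \item A base static cut at \code{cutHeight} (a fraction of the maximum
#'     merge height) yields candidate branches; branches smaller than
#'     \code{minModuleSize} are dissolved into the unassigned label 0.
#'   \item Each candidate branch is split recursively at its top merges. A
#'     merge is split when both sub-branches hold at least
#'     \code{minModuleSize} features, are internally tight (normalized core
#'     scatter at most \code{maxCoreScatter}) and are separated from the
#'     join by a gap -- join height minus the sub-branch's core scatter --
#'     of at least \code{minGap}. Scatter and gap are expressed as
#'     fractions of the distance between the cut height and the 5th
#'     percentile of merge heights. Oversplit fragments of one true module
#'     are re-fused downstream by \code{\link{mergeCloseModules}}. \code{deepSplit} 0--4 interpolates \code{maxCoreScatter}
#'     through 0.64, 0.73, 0.82, 0.91, 0.95 with \code{minGap = (1 -
#'     maxCoreScatter) * 3/4}: higher values split more aggressively into
#'     smaller, tighter modules.
#'   \item When a merge joins a branch smaller than \code{minModuleSize} to
#'     a larger one, the small branch is absorbed if its join height sits
#'     within \code{minGap} of the large branch's core scatter, and sent to
#'     the unassigned label otherwise.
#'   \item With \code{pamStage = TRUE}, each unassigned feature is
#'     re-assigned to the module with the smallest average dissimilarity,
#'     provided that is smaller than the feature's average dissimilarity to
#'     all other features.
#' }
#' Final labels are ordered by decreasing module size and rendered with the
#' conventional module color sequence (0 = \code{"grey"}).
#'
#' @param dendro \code{\link[stats]{hclust}} tree from
#'   \code{\link{clusterFeatures}}.
#' @param diss the dissimilarity matrix the tree was built from.
#' @param minModuleSize smallest admissible module, default 30.
#' @param deepSplit integer 0--4 controlling split sensitivity, default 2.
#' @param pamStage logical; run the assignment rescue stage (default
#'   \code{TRUE}).
#' @param cutHeight base static cut as a fraction of the maximum merge
#'   height, default 0.99.
#' @return a \linkS4class{ModuleSet}.
#' @examples
#' d <- 1 - diag(60)
#' d[1:30, 1:30] <- 0.1; d[31:60, 31:60] <- 0.1; diag(d) <- 0
#' dimnames(d) <- list(paste0("g", 1:60), paste0("g", 1:60))
#' hc <- clusterFeatures(d)
#' cutModules(hc, d, minModuleSize = 10)
#' @export
cutModules <- function(dendro, diss, minModuleSize = 30L, deepSplit = 2L,
                       pamStage = TRUE, cutHeight = 0.99) {
    if (!inherits(dendro, "hclust"))
        stop("dendro must be an hclust object")
    if (minModuleSize < 2L)
        stop("minModuleSize must be >= 2")
    if (!deepSplit %in% 0:4)
        stop("deepSplit must be an integer in 0..4")
    n <- length(dendro$order)
    ids <- dendro$labels
    if (is.null(ids)) ids <- as.character(seq_len(n))
    if (minModuleSize > n) {
        warning("minModuleSize (", minModuleSize, ") exceeds the number of ",
                "features (", n, "); all features left unassigned")
        return(.newModuleSet(stats::setNames(rep(0L, n), ids), dendro,
                             list(minModuleSize = minModuleSize,
                                  deepSplit = deepSplit,
                                  pamStage = pamStage,
                                  cutHeight = cutHeight)))
    }
    maxCoreScatter <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deepSplit + 1L]
    minGap <- (1 - maxCoreScatter) * 3 / 4
    hMax <- max(dendro$height)
    cutH <- cutHeight * hMax
    # scatter and gap are expressed as fractions of the distance between the
    # cut height and the 5th percentile of merge heights
    q5 <- stats::quantile(dendro$height, 0.05, names = FALSE)
    ref <- max(cutH - q5, .Machine$double.eps)
    nodes <- .treeIndex(dendro)

    splitNode <- function(nodeRef) {
        leaves <- .childLeaves(nodes, nodeRef)
        if (length(leaves) < minModuleSize)
            return(list(modules = list(), grey = leaves))
        if (nodeRef < 0)
            return(list(modules = list(leaves), grey = integer()))
        kids <- nodes[[nodeRef]]$children
        l1 <- .childLeaves(nodes, kids[1L]); s1 <- length(l1)
        l2 <- .childLeaves(nodes, kids[2L]); s2 <- length(l2)
        joinH <- nodes[[nodeRef]]$height
        if (s1 >= minModuleSize && s2 >= minModuleSize) {
            ok <- vapply(kids, function(k) {
                cs <- .coreScatter(diss, .childLeaves(nodes, k), minModuleSize)
                (cs - q5) / ref <= maxCoreScatter &&
                    (joinH - cs) / ref >= minGap
            }, logical(1))
            if (all(ok)) {
                r1 <- splitNode(kids[1L]); r2 <- splitNode(kids[2L])
                return(list(modules = c(r1$modules, r2$modules),
                            grey = c(r1$grey, r2$grey)))
            }
            return(list(modules = list(leaves), grey = integer()))
        }
        # one side too small: recurse into the big side, decide the small one
        bigRef <- if (s1 >= s2) kids[1L] else kids[2L]
        smallLv <- if (s1 >= s2) l2 else l1
        res <- splitNode(bigRef)
        if (!length(res$modules)) {
            # no substructure below: the whole branch is one module
            return(list(modules = list(leaves), grey = integer()))
        }
        cs <- .coreScatter(diss, .childLeaves(nodes, bigRef), minModuleSize)
        if (length(res$modules) == 1L && (joinH - cs) / ref < minGap) {
            # small branch chains onto a single tight module: absorb it
            res$modules[[1L]] <- c(res$modules[[1L]], smallLv)
        } else {
            res$grey <- c(res$grey, smallLv)
        }
        res
    }

    base <- .cutAtHeight(dendro, cutH)
    labels <- rep(0L, n)
    modules <- list()
    for (cl in unique(base)) {
        members <- which(base == cl)
        if (length(members) < minModuleSize) next
        top <- .topNodeOf(nodes, members, n)
        res <- splitNode(top)
        modules <- c(modules, res$modules)
    }
    for (i in seq_along(modules)) labels[modules[[i]]] <- i
    labels <- stats::setNames(labels, ids)

    if (pamStage && any(labels == 0L) && length(modules)) {
        labels <- .pamAssign(labels, diss)
    }
    labels <- .relabelBySize(labels)
    .newModuleSet(labels, dendro,
                  list(minModuleSize = as.integer(minModuleSize),
                       deepSplit = as.integer(deepSplit),
                       pamStage = pamStage, cutHeight = cutHeight,
                       maxCoreScatter = maxCoreScatter, minGap = minGap))
}

# top node whose leaf set equals the member set (cutree clusters are subtrees);
# a singleton cluster is the negative leaf reference
.topNodeOf <- function(nodes, members, n) {
    if (length(members) == 1L) return(-members)
    sz <- length(members)
    memberSet <- logical(n)
    memberSet[members] <- TRUE
    for (i in seq_along(nodes)) {
        lv <- nodes[[i]]$leaves
        if (length(lv) == sz && all(memberSet[lv])) return(i)
    }
    stop("internal error: cluster is not a dendrogram subtree")
}

# rescue stage: assign unlabeled features to the nearest module when that
# beats their overall average dissimilarity; all decisions are taken against
# the pre-rescue assignment so the result is order-independent
.pamAssign <- function(labels, diss) {
    grey <- which(labels == 0L)
    mods <- sort(unique(labels[labels > 0L]))
    n <- length(labels)
    out <- labels
    for (g in grey) {
        dAll <- sum(diss[g, -g]) / (n - 1L)
        dMod <- vapply(mods, function(m) {
            mean(diss[g, labels == m])
        }, numeric(1))
        best <- which.min(dMod)
        if (dMod[best] < dAll) out[g] <- mods[best]
    }
    out
}

.relabelBySize <- function(labels) {
    mods <- labels[labels > 0L]
    if (!length(mods)) return(labels)
    sizes <- sort(table(mods), decreasing = TRUE)
    remap <- stats::setNames(seq_along(sizes), names(sizes))
    out <- labels
    out[labels > 0L] <- remap[as.character(mods)]
    stats::setNames(as.integer(out), names(labels))
}

# conventional module color sequence; label 0 is always grey
.moduleColorSequence <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "coral")

.colorForLabels <- function(labels) {
    lab <- sort(unique(labels))
    cols <- character(0)
    for (l in lab) {
        cols[as.character(l)] <- if (l == 0L) "grey" else {
            if (l <= length(.moduleColorSequence))
                .moduleColorSequence[l]
            else paste0("module", l)
        }
    }
    cols
}

.newModuleSet <- function(labels, dendro, params) {
    ms <- new("ModuleSet", labels = labels,
              colors = .colorForLabels(labels),
              dendrogram = dendro, params = params)
    validObject(ms)
    ms
}
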