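#' Design a planted-module simulation
#'
#' Specifies a synthetic expression dataset with latent-factor modules:
#' each module m has its own standard-normal factor per sample, and each of
#' its features is \eqn{x = \lambda f_m + \epsilon} with \eqn{\epsilon \sim
#' N(0, \sigma^2)} and loading \eqn{\lambda = \sigma \sqrt{\rho / (1 -
#' \rho)}}, so the expected pairwise correlation within the module is
#' exactly \eqn{\rho} = \code{withinModuleCor}. Background features are
#' pure noise. Traits respond linearly (or through a logistic threshold for
#' binary traits) to the linked module factors.
#'
#' @param nSamples number of samples.
#' @param moduleSizes features per planted module (may be empty for pure
#'   noise data).
#' @param nBackground unassigned pure-noise features, default 0.
#' @param withinModuleCor target within-module correlation(s) in (0, 1),
#'   recycled across modules; default 0.7.
#' @param noiseSd feature noise standard deviation, default 1.
#' @param traitLinks data.frame with columns \code{module}, \code{trait},
#'   \code{effect}, and optionally \code{type} (\code{"numeric"}, default,
#'   or \code{"binary"}).
#' @param sharedFactorGroups list of integer vectors; all modules in a
#'   group reuse one latent factor (their eigengenes then correlate near 1,
#'   exercising \code{\link{mergeCloseModules}}).
#' @param seed master seed; every draw derives from it.
#' @return a \linkS4class{SimulationDesign}.
#' @export
simulationDesign <- function(nSamples, moduleSizes = integer(),
                             nBackground = 0L, withinModuleCor = 0.7,
                             noiseSd = 1, traitLinks = NULL,
                             sharedFactorGroups = list(), seed = 1L) {
    if (is.null(traitLinks))
        traitLinks <- data.frame(module = integer(), trait = character(),
                                 effect = numeric(), type = character())
    if (nrow(traitLinks) && is.null(traitLinks$type))
        traitLinks$type <- "numeric"
    d <- new("SimulationDesign",
             nSamples = as.integer(nSamples),
             moduleSizes = as.integer(moduleSizes),
             nBackground = as.integer(nBackground),
             withinModuleCor = as.numeric(withinModuleCor),
             noiseSd = as.numeric(noiseSd),
             traitLinks = traitLinks,
             sharedFactorGroups = sharedFactorGroups,
             seed = as.integer(seed))
    validObject(d)
    d
}

#' Simulate expression data with planted co-expression modules
#'
#' Draws a dataset from a \linkS4class{SimulationDesign}. Fully
#' reproducible: the same design (including seed) yields bit-identical
#' output. Trait covariates are attached to the dataset's sample metadata.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @return list with \code{dataset} (a \linkS4class{CoexDataSet}),
#'   \code{trueLabels} (named integer vector, 0 = background),
#'   \code{trueFactors} (modules x samples matrix).
#' @examples
#' sim <- simulateExpression(simulationDesign(20, c(10, 10), seed = 3))
#' table(sim$trueLabels)
#' @export
simulateExpression <- function(design) {
    stopifnot(is(design, "SimulationDesign"))
    validObject(design)
    nS <- design@nSamples
    sizes <- design@moduleSizes
    nMod <- length(sizes)
    rho <- rep_len(design@withinModuleCor, max(nMod, 1L))
    sigma <- design@noiseSd
    nFeat <- sum(sizes) + design@nBackground

    set.seed(design@seed)
    # latent factors, honoring shared-factor groups
    factorOf <- seq_len(nMod)
    for (g in design@sharedFactorGroups)
        factorOf[g] <- min(g)
    uniqueFac <- unique(factorOf)
    fac <- matrix(stats::rnorm(length(uniqueFac) * nS), length(uniqueFac), nS)
    rownames(fac) <- as.character(uniqueFac)
    trueFactors <- matrix(0, nMod, nS,
                          dimnames = list(as.character(seq_len(nMod)),
                                          paste0("s", seq_len(nS))))
    for (m in seq_len(nMod))
        trueFactors[m, ] <- fac[as.character(factorOf[m]), ]

    m <- matrix(NA_real_, nS, nFeat)
    labels <- integer(nFeat)
    col <- 1L
    for (mod in seq_len(nMod)) {
        lambda <- sigma * sqrt(rho[mod] / (1 - rho[mod]))
        for (j in seq_len(sizes[mod])) {
            m[, col] <- lambda * trueFactors[mod, ] +
                stats::rnorm(nS, sd = sigma)
            labels[col] <- mod
            col <- col + 1L
        }
    }
    if (design@nBackground > 0L) {
        m[, col:nFeat] <- stats::rnorm(nS * design@nBackground, sd = sigma)
        labels[col:nFeat] <- 0L
    }
    sampleIds <- paste0("s", seq_len(nS))
    featureIds <- sprintf("g%04d", seq_len(nFeat))
    dimnames(m) <- list(sampleIds, featureIds)
    labels <- stats::setNames(labels, featureIds)

    meta <- data.frame(row.names = sampleIds)
    tl <- design@traitLinks
    if (nrow(tl)) {
        for (i in seq_len(nrow(tl))) {
            f <- trueFactors[tl$module[i], ]
            if (tl$type[i] == "numeric") {
                meta[[tl$trait[i]]] <- tl$effect[i] * f + stats::rnorm(nS)
            } else {
                pr <- stats::plogis(tl$effect[i] * f)
                meta[[tl$trait[i]]] <- factor(
                    ifelse(stats::runif(nS) < pr, "case", "control"),
                    levels = c("control", "case"))
            }
        }
    }
    ds <- CoexDataSet(m, sampleMeta = if (ncol(meta)) meta else NULL)
    list(dataset = ds, trueLabels = labels, trueFactors = trueFactors)
}

#' ModuleSet from ground-truth labels
#'
#' Wraps the \code{trueLabels} of a simulation as a
#' \linkS4class{ModuleSet} (no dendrogram), e.g. to compute eigengenes of
#' the planted modules directly.
#'
#' @param sim result of \code{\link{simulateExpression}}, or a named
#'   integer label vector.
#' @return a \linkS4class{ModuleSet}.
#' @export
trueModuleSet <- function(sim) {
    labels <- if (is.list(sim)) sim$trueLabels else sim
    .newModuleSet(as.integer(labels) |> stats::setNames(names(labels)),
                  NULL, list(source = "ground-truth"))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same features,
#' computed with the closed-form pair-counting formula from the
#' contingency table. The unassigned label 0 counts as its own class.
#'
#' @param a,b label vectors over the same features (matched by name when
#'   both are named).
#' @return ARI in \eqn{[-1, 1]}; 1 means identical partitions.
#' @export
adjustedRandIndex <- function(a, b) {
    if (!is.null(names(a)) && !is.null(names(b))) {
        if (!setequal(names(a), names(b)))
            stop("label vectors cover different features")
        b <- b[names(a)]
    } else if (length(a) != length(b)) {
        stop("label vectors differ in length")
    }
    tab <- table(a, b)
    nij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    nn <- choose(sum(tab), 2)
    expected <- ai * bj / nn
    maxIdx <- (ai + bj) / 2
    if (maxIdx == expected) return(1)   # both partitions trivial
    (nij - expected) / (maxIdx - expected)
}

#' Evaluate module recovery against planted labels
#'
#' @param trueLabels named integer vector of planted labels (0 =
#'   background).
#' @param detected a \linkS4class{ModuleSet} or named label vector over the
#'   same features.
#' @return list with \code{ari} and \code{perModuleJaccard} (data.frame:
#'   planted module, best-matching detected module, Jaccard of the match).
#' @export
evaluateRecovery <- function(trueLabels, detected) {
    det <- if (is(detected, "ModuleSet")) moduleLabels(detected) else detected
    if (!setequal(names(trueLabels), names(det)))
        stop("true and detected labelings cover different features")
    det <- det[names(trueLabels)]
    ari <- adjustedRandIndex(trueLabels, det)
    mods <- sort(unique(trueLabels[trueLabels > 0L]))
    rows <- lapply(mods, function(m) {
        A <- names(trueLabels)[trueLabels == m]
        cand <- sort(unique(det[det > 0L]))
        if (!length(cand))
            return(data.frame(plantedModule = m, bestMatch = NA_integer_,
                              jaccard = 0))
        jac <- vapply(cand, function(d) {
            B <- names(det)[det == d]
            length(intersect(A, B)) / length(union(A, B))
        }, numeric(1))
        best <- which.max(jac)
        data.frame(plantedModule = m, bestMatch = cand[best],
                   jaccard = jac[best])
    })
    list(ari = ari, perModuleJaccard = do.call(rbind, rows))
}
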