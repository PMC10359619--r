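#' One-hot encode traits for correlation
#'
#' Numeric columns pass through; categorical columns (character, factor,
#' logical) expand into one 0/1 indicator per level. Used internally by
#' \code{\link{moduleTraitCorrelation}}; exported because the encoding map
#' is part of the result contract.
#'
#' @param sampleMeta data.frame (or DataFrame) of traits, rows = samples.
#' @return list with \code{traits} (numeric matrix, samples x encoded
#'   traits) and \code{encoding} (named list mapping each categorical
#'   column to its indicator column names).
#' @export
encodeTraits <- function(sampleMeta) {
    if (is(sampleMeta, "DataFrame")) sampleMeta <- as.data.frame(sampleMeta)
    stopifnot(is.data.frame(sampleMeta))
    cols <- list()
    encoding <- list()
    for (nm in colnames(sampleMeta)) {
        v <- sampleMeta[[nm]]
        if (is.numeric(v)) {
            cols[[nm]] <- as.numeric(v)
        } else {
            v <- as.factor(v)
            inds <- paste0(nm, ".", levels(v))
            for (i in seq_along(levels(v)))
                cols[[inds[i]]] <- as.numeric(v == levels(v)[i])
            encoding[[nm]] <- inds
        }
    }
    traits <- do.call(cbind, cols)
    rownames(traits) <- rownames(sampleMeta)
    list(traits = traits, encoding = encoding)
}

#' Module-trait correlation
#'
#' Correlates every module eigengene with every (encoded) trait. The
#' two-sided p-value comes from the t statistic \eqn{t = r \sqrt{(n - 2) /
#' (1 - r^2)}} on \eqn{n - 2} degrees of freedom; Benjamini-Hochberg
#' adjustment is applied across the whole module-by-trait grid. Constant
#' trait columns yield \code{NA} cells with a warning.
#'
#' @param eig an \linkS4class{EigengeneSet}.
#' @param sampleMeta trait table whose rows align with the eigengene
#'   samples (matched by row name when present).
#' @param method only \code{"pearson"}.
#' @return data.frame with columns \code{module}, \code{trait}, \code{r},
#'   \code{p}, \code{padj}; attribute \code{"encoding"} carries the
#'   categorical indicator map.
#' @examples
#' sim <- simulateExpression(simulationDesign(40, c(20, 20), seed = 2,
#'     traitLinks = data.frame(module = 1, trait = "score", effect = 1,
#'                             type = "numeric")))
#' eg <- computeEigengenes(sim$dataset, trueModuleSet(sim))
#' moduleTraitCorrelation(eg, as.data.frame(sampleData(sim$dataset)))
#' @export
moduleTraitCorrelation <- function(eig, sampleMeta, method = "pearson") {
    method <- match.arg(method, "pearson")
    e <- eigengenes(eig)
    n <- ncol(e)
    if (n < 3L)
        stop("module-trait correlation needs at least 3 samples")
    if (is(sampleMeta, "DataFrame")) sampleMeta <- as.data.frame(sampleMeta)
    if (!is.null(rownames(sampleMeta)) &&
        all(colnames(e) %in% rownames(sampleMeta)))
        sampleMeta <- sampleMeta[colnames(e), , drop = FALSE]
    else if (nrow(sampleMeta) != n)
        stop("sampleMeta rows do not match the eigengene samples")
    enc <- encodeTraits(sampleMeta)
    traits <- enc$traits
    const <- apply(traits, 2L, function(v) stats::var(v) == 0)
    if (any(const))
        warning("constant trait column(s) marked undefined: ",
                paste(colnames(traits)[const], collapse = ", "))
    grid <- expand.grid(module = rownames(e), trait = colnames(traits),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rr <- mapply(function(mod, tr) {
        if (const[[tr]]) return(NA_real_)
        stats::cor(e[mod, ], traits[, tr])
    }, grid$module, grid$trait)
    tt <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
    pp <- 2 * stats::pt(-abs(tt), df = n - 2)
    pp[!is.na(rr) & abs(rr) >= 1] <- 0
    out <- data.frame(grid, r = unname(rr), p = unname(pp))
    out$padj <- stats::p.adjust(out$p, method = "BH")
    attr(out, "encoding") <- enc$encoding
    out
}

#' Summarize eigengene expression by a sample category
#'
#' Per module and category level: mean, standard deviation and sample count
#' of the eigengene, plus the per-sample values for plotting.
#'
#' @param eig an \linkS4class{EigengeneSet}.
#' @param sampleMeta trait table aligned with the eigengene samples.
#' @param category name of a categorical column of \code{sampleMeta}.
#' @return list with \code{summary} (data.frame: module, level, mean, sd, n)
#'   and \code{samples} (data.frame: module, sample, level, value).
#' @export
summarizeEigengeneByCategory <- function(eig, sampleMeta, category) {
    if (is(sampleMeta, "DataFrame")) sampleMeta <- as.data.frame(sampleMeta)
    if (!category %in% colnames(sampleMeta))
        stop("unknown category column: ", category)
    e <- eigengenes(eig)
    if (!is.null(rownames(sampleMeta)) &&
        all(colnames(e) %in% rownames(sampleMeta)))
        sampleMeta <- sampleMeta[colnames(e), , drop = FALSE]
    else if (nrow(sampleMeta) != ncol(e))
        stop("sampleMeta rows do not match the eigengene samples")
    lev <- as.factor(sampleMeta[[category]])
    samples <- data.frame(
        module = rep(rownames(e), each = ncol(e)),
        sample = rep(colnames(e), times = nrow(e)),
        level = rep(as.character(lev), times = nrow(e)),
        value = as.vector(t(e)))
    agg <- do.call(rbind, lapply(split(samples, samples[c("module", "level")]),
        function(d) data.frame(module = d$module[1L], level = d$level[1L],
                               mean = mean(d$value),
                               sd = if (nrow(d) > 1L) stats::sd(d$value) else NA_real_,
                               n = nrow(d))))
    rownames(agg) <- NULL
    agg <- agg[order(agg$module, agg$level), ]
    list(summary = agg, samples = samples)
}

#' Module membership (kME) and intramodular connectivity
#'
#' kME is the Pearson correlation of each feature's expression profile with
#' each module eigengene; intramodular connectivity is the sum of a
#' feature's adjacency to the other features of its own module.
#'
#' @param ds a \linkS4class{CoexDataSet}.
#' @param eig an \linkS4class{EigengeneSet} over the same samples.
#' @param net a \linkS4class{CoexNetwork} over the same features.
#' @param modules a \linkS4class{ModuleSet}.
#' @return list with \code{kME} (features x modules matrix),
#'   \code{intramodularConnectivity} (named numeric per feature; 0 for
#'   unassigned features) and \code{ownModule} (named integer labels).
#' @export
moduleMembership <- function(ds, eig, net, modules) {
    m <- exprMatrix(ds)
    e <- eigengenes(eig)
    if (!identical(colnames(e), rownames(m)))
        stop("eigengene samples do not match the dataset samples")
    labels <- moduleLabels(modules)
    feats <- colnames(m)
    if (!identical(sort(names(labels)), sort(feats)))
        stop("module assignment features do not match the dataset features")
    kME <- stats::cor(m, t(e))
    adj <- adjacencyMatrix(net)
    if (!identical(rownames(adj), feats))
        adj <- adj[feats, feats]
    kIn <- stats::setNames(numeric(length(feats)), feats)
    for (mod in unique(labels[labels > 0L])) {
        idx <- names(labels)[labels == mod]
        sub <- adj[idx, idx, drop = FALSE]
        kIn[idx] <- rowSums(sub) - 1
    }
    list(kME = kME, intramodularConnectivity = kIn,
         ownModule = labels[feats])
}

#' Hub genes per module
#'
#' Ranks each module's features by kME to the module's own eigengene
#' (descending), breaking ties by intramodular connectivity (descending)
#' and then by feature identifier (lexicographic). Returns up to
#' \code{topN} features per module; smaller modules return all members.
#'
#' @param membership result of \code{\link{moduleMembership}}.
#' @param modules a \linkS4class{ModuleSet}.
#' @param topN number of hubs per module, default 10.
#' @return named list (one entry per module label) of data.frames with
#'   columns \code{feature}, \code{kME}, \code{intramodularConnectivity}.
#' @export
hubGenes <- function(membership, modules, topN = 10L) {
    if (topN < 1L) stop("topN must be >= 1")
    labels <- moduleLabels(modules)
    out <- list()
    for (mod in sort(unique(labels[labels > 0L]))) {
        feats <- names(labels)[labels == mod]
        km <- membership$kME[feats, as.character(mod)]
        kin <- membership$intramodularConnectivity[feats]
        ord <- order(-km, -kin, feats)
        take <- utils::head(ord, topN)
        out[[as.character(mod)]] <- data.frame(
            feature = feats[take], kME = unname(km[take]),
            intramodularConnectivity = unname(kin[take]))
    }
    out
}
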