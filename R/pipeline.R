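#' Read / write a pipeline run configuration
#'
#' The run configuration is a plain-text YAML document with one section per
#' stage (\code{input}, \code{preprocess}, \code{network}, \code{modules},
#' \code{stats}) plus \code{seed} and \code{outDir}. Writing then reading a
#' configuration returns an equal object (round-trip contract).
#'
#' @param path file path.
#' @param config named list as produced by \code{\link{defaultRunConfig}}.
#' @return \code{readRunConfig}: the configuration list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' Default pipeline configuration
#'
#' @param exprFile expression matrix path (CSV/TSV).
#' @param outDir output directory.
#' @param orientation \code{"samples"} or \code{"features"} in rows.
#' @param sampleMetaFile optional sample metadata path.
#' @param seed master seed recorded with the run.
#' @return nested configuration list; every entry can be edited before
#'   \code{\link{runPipeline}}.
#' @export
defaultRunConfig <- function(exprFile, outDir, orientation = "samples",
                             sampleMetaFile = NULL, seed = 1L) {
    list(
        version = as.character(utils::packageVersion("coexmods")),
        seed = as.integer(seed),
        outDir = outDir,
        input = list(exprFile = exprFile, orientation = orientation,
                     delimiter = NULL, sampleMetaFile = sampleMetaFile),
        preprocess = list(minTotalExpression = 1, maxMissingFraction = 0.5,
                          sampleCutHeight = NULL),
        network = list(power = "auto", networkType = "signed",
                       corMethod = "pearson", tomType = "signed",
                       fitCutoff = 0.9),
        modules = list(minModuleSize = 30L, deepSplit = 2L, pamStage = TRUE,
                       cutHeight = 0.99, mergeCutHeight = 0.25),
        stats = list(category = NULL, topHubs = 10L)
    )
}

.stage <- function(name, expr, log) {
    log(sprintf("stage %s: start", name))
    res <- tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
    log(sprintf("stage %s: done", name))
    res
}

#' Run the full co-expression pipeline
#'
#' Executes ingest, preprocessing, network construction, module detection
#' (with merging) and module statistics in order, writing every artifact as
#' a plain-text table into the output directory together with a snapshot of
#' the configuration. Rerunning with an identical configuration and inputs
#' reproduces identical module assignments.
#'
#' Outputs written to \code{config$outDir}: \code{config.yaml},
#' \code{run.log}, \code{qc_report.txt}, \code{soft_threshold.tsv},
#' \code{module_assignment.tsv}, \code{eigengenes.tsv},
#' \code{trait_correlation.tsv} (when sample metadata exist),
#' \code{hub_genes.tsv}.
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}}) or
#'   path to a YAML config file.
#' @return invisibly, a list with the in-memory results: \code{dataset},
#'   \code{network}, \code{modules}, \code{eigengenes}, \code{softThreshold},
#'   \code{traitCorrelation}, \code{hubs}, \code{outDir}.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    outDir <- config$outDir
    if (is.null(outDir)) stop("config$outDir is required")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logFile <- file.path(outDir, "run.log")
    cat(sprintf("# run started %s\n", format(Sys.time())), file = logFile)
    log <- function(msg) {
        line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
        message(line)
        cat(line, "\n", file = logFile, append = TRUE)
    }
    writeRunConfig(config, file.path(outDir, "config.yaml"))
    log(paste("parameters:", paste(deparse(config), collapse = " ")))
    set.seed(config$seed %||% 1L)

    ds <- .stage("ingest", {
        inp <- config$input
        if (is.null(inp$exprFile) || !file.exists(inp$exprFile))
            stop("expression input not found: ",
                 if (is.null(inp$exprFile)) "(unset)" else inp$exprFile)
        d <- readExpression(inp$exprFile,
                            orientation = inp$orientation %||% "samples",
                            delimiter = inp$delimiter)
        if (!is.null(inp$sampleMetaFile)) {
            if (!file.exists(inp$sampleMetaFile))
                stop("sample metadata not found: ", inp$sampleMetaFile)
            d <- attachMetadata(d, data.table::fread(inp$sampleMetaFile,
                                                     data.table = FALSE),
                                "sample")
        }
        d
    }, log)

    pre <- .stage("preprocess", {
        pp <- config$preprocess
        res <- filterFeatures(ds, pp$minTotalExpression %||% 1,
                              pp$maxMissingFraction %||% 0.5)
        reports <- list(res$report)
        if (!is.null(pp$sampleCutHeight)) {
            res2 <- detectOutlierSamples(res$dataset, pp$sampleCutHeight)
            res$dataset <- res2$dataset
            reports <- c(reports, list(res2$report))
        }
        sink(file.path(outDir, "qc_report.txt"))
        for (r in reports) show(r)
        sink()
        res$dataset
    }, log)

    net <- .stage("network", {
        nw <- config$network
        power <- nw$power %||% "auto"
        sft <- NULL
        if (identical(power, "auto")) {
            sft <- pickSoftThreshold(pre, networkType = nw$networkType %||% "signed",
                                     corMethod = nw$corMethod %||% "pearson",
                                     fitCutoff = nw$fitCutoff %||% 0.9)
            data.table::fwrite(sft@fitTable,
                               file.path(outDir, "soft_threshold.tsv"),
                               sep = "\t")
            power <- sft@chosenPower
            log(sprintf("chosen soft power: %g", power))
        }
        n <- buildNetwork(pre, power = as.numeric(power),
                          networkType = nw$networkType %||% "signed",
                          corMethod = nw$corMethod %||% "pearson",
                          tomType = nw$tomType %||% "signed")
        attr(n, "softThreshold") <- sft
        n
    }, log)

    det <- .stage("modules", {
        md <- config$modules
        hc <- clusterFeatures(tomDissimilarity(tomMatrix(net)))
        ms <- cutModules(hc, tomDissimilarity(tomMatrix(net)),
                         minModuleSize = md$minModuleSize %||% 30L,
                         deepSplit = md$deepSplit %||% 2L,
                         pamStage = md$pamStage %||% TRUE,
                         cutHeight = md$cutHeight %||% 0.99)
        mch <- md$mergeCutHeight %||% 0.25
        if (any(moduleLabels(ms) > 0L) && mch > 0) {
            merged <- mergeCloseModules(pre, ms, mch)
        } else {
            eg <- if (any(moduleLabels(ms) > 0L))
                computeEigengenes(pre, ms) else NULL
            merged <- list(modules = ms, eigengenes = eg)
        }
        writeModuleAssignment(merged$modules,
                              file.path(outDir, "module_assignment.tsv"))
        if (!is.null(merged$eigengenes)) {
            e <- eigengenes(merged$eigengenes)
            data.table::fwrite(data.table::data.table(module = rownames(e), e),
                               file.path(outDir, "eigengenes.tsv"), sep = "\t")
        }
        merged
    }, log)

    statsOut <- .stage("stats", {
        out <- list(traitCorrelation = NULL, hubs = NULL, summary = NULL)
        if (is.null(det$eigengenes)) return(out)
        meta <- as.data.frame(colData(pre))
        if (ncol(meta)) {
            out$traitCorrelation <- moduleTraitCorrelation(det$eigengenes, meta)
            data.table::fwrite(out$traitCorrelation,
                               file.path(outDir, "trait_correlation.tsv"),
                               sep = "\t")
            cat_ <- config$stats$category
            if (!is.null(cat_))
                out$summary <- summarizeEigengeneByCategory(det$eigengenes,
                                                            meta, cat_)
        }
        mem <- moduleMembership(pre, det$eigengenes, net, det$modules)
        out$hubs <- hubGenes(mem, det$modules,
                             topN = config$stats$topHubs %||% 10L)
        hubTab <- do.call(rbind, lapply(names(out$hubs), function(m)
            cbind(module = m, out$hubs[[m]])))
        data.table::fwrite(hubTab, file.path(outDir, "hub_genes.tsv"),
                           sep = "\t")
        out
    }, log)

    log("run complete")
    invisible(list(dataset = pre, network = net, modules = det$modules,
                   eigengenes = det$eigengenes,
                   softThreshold = attr(net, "softThreshold"),
                   traitCorrelation = statsOut$traitCorrelation,
                   hubs = statsOut$hubs, outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a module assignment table
#'
#' Two-way plain-text exchange format: a TSV with columns
#' \code{feature_id}, \code{module_label}, \code{module_color}.
#'
#' @param modules a \linkS4class{ModuleSet}.
#' @param path TSV path.
#' @return \code{readModuleAssignment}: a \linkS4class{ModuleSet} (without
#'   dendrogram).
#' @export
writeModuleAssignment <- function(modules, path) {
    labels <- moduleLabels(modules)
    tab <- data.frame(feature_id = names(labels),
                      module_label = unname(labels),
                      module_color = unname(moduleColors(modules)))
    data.table::fwrite(tab, path, sep = "\t")
    invisible(path)
}

#' @rdname writeModuleAssignment
#' @export
readModuleAssignment <- function(path) {
    tab <- data.table::fread(path, data.table = FALSE)
    labels <- stats::setNames(as.integer(tab$module_label), tab$feature_id)
    colors <- unique(tab[c("module_label", "module_color")])
    ms <- new("ModuleSet", labels = labels,
              colors = stats::setNames(colors$module_color,
                                       as.character(colors$module_label)),
              dendrogram = NULL, params = list(source = path))
    validObject(ms)
    ms
}

#' Detect modules from a dataset and network in one call
#'
#' Convenience wrapper: TOM dissimilarity, average-linkage clustering,
#' adaptive tree cut, then eigengene-based merging.
#'
#' @param ds a \linkS4class{CoexDataSet}.
#' @param net a \linkS4class{CoexNetwork} built from it.
#' @param minModuleSize,deepSplit,pamStage,cutHeight see
#'   \code{\link{cutModules}}.
#' @param mergeCutHeight see \code{\link{mergeCloseModules}}; 0 disables
#'   merging.
#' @return list with \code{modules} and \code{eigengenes}.
#' @export
detectModules <- function(ds, net, minModuleSize = 30L, deepSplit = 2L,
                          pamStage = TRUE, cutHeight = 0.99,
                          mergeCutHeight = 0.25) {
    diss <- tomDissimilarity(tomMatrix(net))
    hc <- clusterFeatures(diss)
    ms <- cutModules(hc, diss, minModuleSize = minModuleSize,
                     deepSplit = deepSplit, pamStage = pamStage,
                     cutHeight = cutHeight)
    if (!any(moduleLabels(ms) > 0L))
        return(list(modules = ms, eigengenes = NULL))
    if (mergeCutHeight > 0)
        mergeCloseModules(ds, ms, mergeCutHeight)
    else
        list(modules = ms, eigengenes = computeEigengenes(ds, ms))
}
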