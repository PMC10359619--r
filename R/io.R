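#' Construct a CoexDataSet from a samples-by-features matrix
#'
#' @param exprs numeric matrix, samples in rows and features in columns, with
#'   identifier dimnames (or supply \code{sampleIds}/\code{featureIds}).
#' @param sampleIds,featureIds optional identifier vectors overriding the
#'   dimnames.
#' @param sampleMeta,featureMeta optional metadata tables keyed by identifier
#'   (data.frame with row names, or with an \code{id} first column).
#' @return a \linkS4class{CoexDataSet}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
#' CoexDataSet(m)
#' @export
CoexDataSet <- function(exprs, sampleIds = rownames(exprs),
                        featureIds = colnames(exprs),
                        sampleMeta = NULL, featureMeta = NULL) {
    if (!is.matrix(exprs) || !is.numeric(exprs))
        stop("exprs must be a numeric matrix (samples x features)")
    if (is.null(sampleIds) || is.null(featureIds))
        stop("sample and feature identifiers are required")
    sampleIds <- trimws(as.character(sampleIds))
    featureIds <- trimws(as.character(featureIds))
    assay <- t(exprs)
    dimnames(assay) <- list(featureIds, sampleIds)
    cd <- S4Vectors::DataFrame(row.names = sampleIds)
    rd <- S4Vectors::DataFrame(row.names = featureIds)
    se <- SummarizedExperiment(assays = list(exprs = assay),
                               colData = cd, rowData = rd)
    ds <- new("CoexDataSet", se)
    validObject(ds)
    if (!is.null(sampleMeta)) ds <- attachMetadata(ds, sampleMeta, "sample")
    if (!is.null(featureMeta)) ds <- attachMetadata(ds, featureMeta, "feature")
    ds
}

.resolveDelimiter <- function(path, delimiter) {
    if (!is.null(delimiter)) return(delimiter)
    ext <- tolower(tools::file_ext(path))
    switch(ext, tsv = "\t", txt = "\t", csv = ",", ",")
}

#' Read an expression matrix from CSV/TSV
#'
#' Reads a delimited text file whose first column holds identifiers and whose
#' remaining cells are numeric expression values, and returns it in the
#' canonical orientation (samples as the observation axis). When the file
#' stores features in rows (the common genes-in-rows export), pass
#' \code{orientation = "features"} and the matrix is transposed on ingestion.
#' Missing values (\code{NA}, empty cells, or a custom marker) are kept as
#' missing, never coerced to zero.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (\code{.csv} comma, \code{.tsv}/\code{.txt} tab) unless given.
#' @param orientation \code{"samples"} if samples are in rows,
#'   \code{"features"} if features are in rows.
#' @param delimiter field separator overriding the extension-based guess.
#' @param naStrings cell values treated as missing.
#' @return a \linkS4class{CoexDataSet}.
#' @section Errors: duplicated identifiers on either axis abort with the
#'   offending identifiers named; a non-numeric cell aborts with its row and
#'   column coordinates.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,g1,g2", "s1,1,2", "s2,3,4", "s3,5,6"), f)
#' ds <- readExpression(f, orientation = "samples")
#' nSamples(ds); nFeatures(ds)
#' @export
readExpression <- function(path, orientation = c("samples", "features"),
                           delimiter = NULL, naStrings = c("NA", "")) {
    orientation <- match.arg(orientation)
    if (!file.exists(path))
        stop("file not found: ", path)
    sep <- .resolveDelimiter(path, delimiter)
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            na.strings = naStrings, colClasses = NULL,
                            data.table = FALSE, check.names = FALSE)
    if (ncol(dt) < 2L)
        stop("expression file needs an identifier column plus >=1 value column")
    rowIds <- trimws(as.character(dt[[1L]]))
    colIds <- trimws(colnames(dt)[-1L])
    if (anyDuplicated(rowIds))
        stop("duplicated identifiers in first column: ",
             paste(unique(rowIds[duplicated(rowIds)]), collapse = ", "))
    if (anyDuplicated(colIds))
        stop("duplicated identifiers in header: ",
             paste(unique(colIds[duplicated(colIds)]), collapse = ", "))
    vals <- dt[-1L]
    bad <- which(!vapply(vals, is.numeric, logical(1)))
    for (j in bad) {
        col <- suppressWarnings(as.numeric(vals[[j]]))
        broken <- which(!is.na(vals[[j]]) & is.na(col))
        if (length(broken))
            stop(sprintf(
                "non-numeric value '%s' at data row %d, column '%s'",
                vals[[j]][broken[1L]], broken[1L], colIds[j]))
        vals[[j]] <- col
    }
    m <- as.matrix(vals)
    dimnames(m) <- list(rowIds, colIds)
    if (orientation == "features") m <- t(m)
    CoexDataSet(m)
}

.keyedTable <- function(table) {
    if (is(table, "DataFrame")) table <- as.data.frame(table)
    if (!is.data.frame(table))
        stop("metadata must be a data.frame or DataFrame")
    if (!is.null(rownames(table)) &&
        !identical(rownames(table), as.character(seq_len(nrow(table)))))
        return(table)
    rownames(table) <- trimws(as.character(table[[1L]]))
    table[, -1L, drop = FALSE]
}

#' Attach sample or feature metadata by identifier
#'
#' Aligns a keyed metadata table to the dataset's sample or feature axis.
#' Rows whose identifier is absent from the dataset are dropped with a
#' warning; dataset identifiers absent from the table receive \code{NA}
#' metadata. A table sharing no identifiers with the dataset is an error.
#'
#' @param ds a \linkS4class{CoexDataSet}.
#' @param table data.frame keyed by row names, or whose first column holds
#'   the identifiers.
#' @param axis \code{"sample"} or \code{"feature"}.
#' @return the dataset with the metadata merged onto the chosen axis.
#' @examples
#' ds <- exampleDataSet()
#' meta <- data.frame(id = rownames(exprMatrix(ds)),
#'                    group = rep(c("a", "b"), length.out = nSamples(ds)))
#' ds <- attachMetadata(ds, meta, "sample")
#' sampleData(ds)
#' @export
attachMetadata <- function(ds, table, axis = c("sample", "feature")) {
    axis <- match.arg(axis)
    table <- .keyedTable(table)
    ids <- if (axis == "sample") colnames(ds) else rownames(ds)
    keys <- trimws(rownames(table))
    hit <- keys %in% ids
    if (!any(hit))
        stop("metadata table shares no identifiers with the dataset ",
             sprintf("(%s axis)", axis))
    if (any(!hit))
        warning(sum(!hit), " metadata row(s) dropped; identifiers not in ",
                "dataset: ", paste(utils::head(keys[!hit], 5L), collapse = ", "))
    aligned <- table[match(ids, keys), , drop = FALSE]
    rownames(aligned) <- ids
    df <- S4Vectors::DataFrame(aligned)
    if (axis == "sample") {
        colData(ds)[colnames(df)] <- df
    } else {
        rowData(ds)[colnames(df)] <- df
    }
    validObject(ds)
    ds
}

#' @importFrom SummarizedExperiment colData<- rowData<-
NULL

#' Write / read a dataset as plain-text tables
#'
#' \code{writeDataset} stores the expression matrix (samples in rows) plus
#' the sample and feature metadata as TSV files in a directory;
#' \code{readDataset} restores the dataset so that matrix, identifiers and
#' metadata round-trip exactly.
#'
#' @param ds a \linkS4class{CoexDataSet}.
#' @param dir directory to create/read.
#' @return \code{writeDataset}: the directory, invisibly;
#'   \code{readDataset}: a \linkS4class{CoexDataSet}.
#' @export
writeDataset <- function(ds, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- exprMatrix(ds)
    expr <- data.table::data.table(sample_id = rownames(m), m)
    data.table::fwrite(expr, file.path(dir, "expression.tsv"), sep = "\t")
    sm <- as.data.frame(colData(ds))
    if (ncol(sm)) {
        sm <- cbind(sample_id = rownames(sm), sm)
        data.table::fwrite(sm, file.path(dir, "sample_meta.tsv"), sep = "\t")
    }
    fm <- as.data.frame(rowData(ds))
    if (ncol(fm)) {
        fm <- cbind(feature_id = rownames(fm), fm)
        data.table::fwrite(fm, file.path(dir, "feature_meta.tsv"), sep = "\t")
    }
    invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
    ds <- readExpression(file.path(dir, "expression.tsv"),
                         orientation = "samples", delimiter = "\t")
    sm <- file.path(dir, "sample_meta.tsv")
    if (file.exists(sm))
        ds <- attachMetadata(ds, data.table::fread(sm, data.table = FALSE),
                             "sample")
    fm <- file.path(dir, "feature_meta.tsv")
    if (file.exists(fm))
        ds <- attachMetadata(ds, data.table::fread(fm, data.table = FALSE),
                             "feature")
    ds
}

#' Small deterministic example dataset
#'
#' Convenience constructor used in the documentation examples: two planted
#' modules of 15 features plus 10 background features over 30 samples.
#'
#' @param seed seed for the generator.
#' @return a \linkS4class{CoexDataSet}.
#' @export
exampleDataSet <- function(seed = 7L) {
    des <- simulationDesign(nSamples = 30L, moduleSizes = c(15L, 15L),
                            nBackground = 10L, withinModuleCor = 0.8,
                            seed = seed)
    simulateExpression(des)$dataset
}
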