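# Small in-code fixtures shared across test files.

writeTinyCSV <- function(lines, ext = ".csv") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}

# 3 samples x 2 features, samples in rows
tinyExprFile <- function() {
    writeTinyCSV(c("id,g1,g2", "s1,1,2", "s2,3,4", "s3,5,6"))
}

# block-structured dissimilarity: within-block `lo`, between `hi`
blockDiss <- function(blockSizes, lo = 0.1, hi = 0.9) {
    n <- sum(blockSizes)
    lab <- rep(seq_along(blockSizes), blockSizes)
    d <- matrix(hi, n, n)
    for (b in seq_along(blockSizes))
        d[lab == b, lab == b] <- lo
    diag(d) <- 0
    ids <- sprintf("g%03d", seq_len(n))
    dimnames(d) <- list(ids, ids)
    list(diss = d, labels = stats::setNames(lab, ids))
}
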