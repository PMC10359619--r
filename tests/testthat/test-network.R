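test_that("pairwise correlation matches hand-computed values", {
    m <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 3, 2, 4))
    rownames(m) <- paste0("s", 1:4)
    ds <- CoexDataSet(m)
    cc <- pairwiseCorrelation(ds)
    expect_equal(unname(diag(cc)), rep(1, 3))
    expect_equal(cc["a", "b"], -1)
    expect_equal(cc["a", "c"], 0.8)   # cov 4/3, var 5/3 each
    expect_equal(cc, t(cc))
})

test_that("correlation rejects missing data and zero-variance features", {
    m <- cbind(a = c(1, 2, NA), b = c(4, 3, 2), c = c(2, 2, 3))
    rownames(m) <- paste0("s", 1:3)
    expect_error(pairwiseCorrelation(CoexDataSet(m)), "missing")
    m2 <- cbind(a = c(1, 2, 3), flat = c(5, 5, 5))
    rownames(m2) <- paste0("s", 1:3)
    expect_error(pairwiseCorrelation(CoexDataSet(m2)), "flat")
})

test_that("correlation is invariant to permuting samples", {
    ds <- exampleDataSet(seed = 5L)
    m <- exprMatrix(ds)
    perm <- sample(nrow(m))
    expect_equal(pairwiseCorrelation(CoexDataSet(m[perm, ])),
                 pairwiseCorrelation(ds))
})

test_that("biweight midcorrelation tracks Pearson on clean data and resists outliers", {
    set.seed(9)
    f <- rnorm(60)
    m <- cbind(a = f + rnorm(60, sd = 0.3), b = f + rnorm(60, sd = 0.3),
               c = rnorm(60))
    rownames(m) <- paste0("s", 1:60)
    bc <- pairwiseCorrelation(CoexDataSet(m), method = "bicor")
    pc <- pairwiseCorrelation(CoexDataSet(m), method = "pearson")
    expect_equal(bc["a", "b"], pc["a", "b"], tolerance = 0.1)
    expect_true(all(abs(bc) <= 1))
    # one wild outlier wrecks Pearson but not bicor
    m2 <- m
    m2[1, "c"] <- 500
    m2[1, "a"] <- 500
    bc2 <- pairwiseCorrelation(CoexDataSet(m2), method = "bicor")
    pc2 <- pairwiseCorrelation(CoexDataSet(m2), method = "pearson")
    expect_gt(pc2["a", "c"], 0.9)
    expect_lt(abs(bc2["a", "c"]), 0.3)
})

test_that("adjacency transforms match their closed forms", {
    r <- matrix(c(1, 0.5, -1, 0.5, 1, 0, -1, 0, 1), 3)
    expect_equal(adjacencyFromCorrelation(r, 6, "unsigned")[1, 2], 0.5^6)
    expect_equal(adjacencyFromCorrelation(r, 6, "unsigned")[1, 2], 0.015625)
    expect_equal(adjacencyFromCorrelation(r, 3, "signed")[1, 3], 0)
    expect_equal(adjacencyFromCorrelation(r, 3, "signed")[1, 2], 0.75^3)
    expect_equal(adjacencyFromCorrelation(r, 2, "signed-hybrid")[1, 3], 0)
    expect_equal(adjacencyFromCorrelation(r, 2, "signed-hybrid")[1, 2], 0.25)
    a <- adjacencyFromCorrelation(r, 6, "signed")
    expect_equal(unname(diag(a)), rep(1, 3))
    expect_error(adjacencyFromCorrelation(r, 0), "positive")
})

test_that("adjacency entries shrink as the power grows", {
    set.seed(21)
    ds <- exampleDataSet(seed = 21L)
    r <- pairwiseCorrelation(ds)
    off <- upper.tri(r)
    for (type in c("unsigned", "signed", "signed-hybrid")) {
        a2 <- adjacencyFromCorrelation(r, 2, type)
        a5 <- adjacencyFromCorrelation(r, 5, type)
        expect_true(all(a5[off] <= a2[off] + 1e-15))
    }
})

test_that("TOM limits: complete graph gives 1, empty graph gives 0", {
    n <- 6
    full <- matrix(1, n, n)
    expect_equal(tomSimilarity(full), matrix(1, n, n), ignore_attr = TRUE)
    empty <- diag(n)
    tome <- tomSimilarity(empty)
    expect_equal(unname(diag(tome)), rep(1, n))
    expect_equal(unname(tome[upper.tri(tome)]), rep(0, n * (n - 1) / 2))
})

test_that("vectorized TOM equals the triple-loop brute force", {
    set.seed(123)
    for (rep in 1:10) {
        n <- sample(5:20, 1)
        a <- randomAdjacency(n)
        tom <- tomSimilarity(a)
        expect_lt(max(abs(tom - bruteTOM(a))), 1e-12)
        expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
        expect_equal(tom, t(tom), ignore_attr = TRUE)
    }
})

test_that("TOM dissimilarity is the complement with a zero diagonal", {
    a <- randomAdjacency(8)
    tom <- tomSimilarity(a)
    d <- tomDissimilarity(tom)
    expect_equal(unname(diag(d)), rep(0, 8))
    off <- upper.tri(d)
    expect_equal(d[off], 1 - tom[off])
    expect_error(tomSimilarity(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("soft-threshold selection reports a fit and monotone connectivity", {
    sim <- simulateExpression(simulationDesign(
        40, rep(50L, 4), nBackground = 0L, withinModuleCor = 0.8, seed = 77L))
    rep_ <- suppressWarnings(pickSoftThreshold(sim$dataset, powers = c(1:8),
                                               fitCutoff = 0.8))
    tab <- rep_@fitTable
    expect_true(all(diff(tab$meanConnectivity) <= 1e-10))
    expect_true(rep_@chosenPower %in% tab$power)
    if (rep_@cutoffMet)
        expect_gte(tab$scaleFreeR2[tab$power == rep_@chosenPower], 0.8)
    expect_error(pickSoftThreshold(sim$dataset, powers = numeric(0)),
                 "non-empty")
})

test_that("buildNetwork bundles consistent matrices and parameters", {
    ds <- exampleDataSet(seed = 4L)
    net <- buildNetwork(ds, power = 6)
    expect_s4_class(net, "CoexNetwork")
    expect_equal(softPower(net), 6)
    expect_equal(adjacencyMatrix(net),
                 adjacencyFromCorrelation(correlationMatrix(net), 6, "signed"))
    expect_true(validObject(net))
})
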