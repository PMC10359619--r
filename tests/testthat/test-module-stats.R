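eigFromVectors <- function(v) {
    # wrap rows of v (modules x samples) as a valid EigengeneSet
    z <- t(apply(v, 1, function(x) as.numeric(scale(x))))
    dimnames(z) <- dimnames(v)
    new("EigengeneSet", eigengenes = z,
        varianceExplained = stats::setNames(rep(1, nrow(v)), rownames(v)),
        orientationSign = stats::setNames(rep(1, nrow(v)), rownames(v)))
}

test_that("module-trait correlation matches the t-distribution oracle", {
    set.seed(61)
    n <- 20
    e <- matrix(rnorm(2 * n), 2, n,
                dimnames = list(c("1", "2"), paste0("s", 1:n)))
    eig <- eigFromVectors(e)

    # trait identical to an eigengene: r = 1, p ~ 0
    meta <- data.frame(tr = eigengenes(eig)["1", ],
                       row.names = colnames(eigengenes(eig)))
    res <- moduleTraitCorrelation(eig, meta)
    row1 <- res[res$module == "1" & res$trait == "tr", ]
    expect_equal(row1$r, 1, tolerance = 1e-12)
    expect_lt(row1$p, 1e-12)

    # orthogonal trait: r = 0 exactly => p = 1
    e1 <- eigengenes(eig)["1", ]
    orth <- rnorm(n)
    orth <- as.numeric(scale(residuals(lm(orth ~ e1))))
    meta2 <- data.frame(tr = orth, row.names = names(e1))
    res2 <- moduleTraitCorrelation(eig, meta2)
    expect_equal(res2[res2$module == "1", "p"], 1, tolerance = 1e-8)

    # r = 0.5 at n = 20: compare p against numeric integration of the t density
    target <- 0.5
    base <- as.numeric(scale(rnorm(n)))
    mix <- target * e1 / sd(e1) + sqrt(1 - target^2) *
        as.numeric(scale(residuals(lm(base ~ e1))))
    # construct a trait with exact sample correlation 0.5 to eigengene 1
    meta3 <- data.frame(tr = mix, row.names = names(e1))
    res3 <- moduleTraitCorrelation(eig, meta3)
    row3 <- res3[res3$module == "1", ]
    expect_equal(row3$r, 0.5, tolerance = 1e-10)
    expect_equal(row3$p, tTestPOracle(0.5, n), tolerance = 1e-8)
    expect_equal(row3$p, 0.0247696, tolerance = 1e-5)

    # BH-adjusted p never smaller than raw p
    expect_true(all(res3$padj >= res3$p - 1e-15))
})

test_that("categorical traits are one-hot encoded and constants flagged", {
    set.seed(62)
    e <- matrix(rnorm(40), 2, 20,
                dimnames = list(c("1", "2"), paste0("s", 1:20)))
    eig <- eigFromVectors(e)
    meta <- data.frame(genotype = rep(c("WT", "MUT"), each = 10),
                       flat = rep(1, 20),
                       row.names = colnames(eigengenes(eig)))
    expect_warning(res <- moduleTraitCorrelation(eig, meta), "flat")
    expect_setequal(unique(res$trait),
                    c("genotype.MUT", "genotype.WT", "flat"))
    expect_true(all(is.na(res[res$trait == "flat", "r"])))
    enc <- attr(res, "encoding")
    expect_equal(enc$genotype, c("genotype.MUT", "genotype.WT"))
    # the two indicator columns are perfectly anti-correlated
    wt <- res[res$trait == "genotype.WT" & res$module == "1", "r"]
    mut <- res[res$trait == "genotype.MUT" & res$module == "1", "r"]
    expect_equal(wt, -mut, tolerance = 1e-12)
})

test_that("eigengene summaries by category report level means and counts", {
    val <- sqrt(9 / 10)   # +-1 pattern rescaled to unit sample variance
    e <- matrix(c(rep(val, 5), rep(-val, 5)), 1, 10,
                dimnames = list("1", paste0("s", 1:10)))
    eig <- new("EigengeneSet", eigengenes = e,
               varianceExplained = c("1" = 1),
               orientationSign = c("1" = 1))
    meta <- data.frame(group = rep(c("hi", "lo"), each = 5),
                       row.names = colnames(e))
    out <- summarizeEigengeneByCategory(eig, meta, "group")
    s <- out$summary
    expect_equal(s$n, c(5L, 5L))
    expect_equal(s$mean[s$level == "hi"], val)
    expect_equal(s$mean[s$level == "lo"], -val)
    expect_equal(nrow(out$samples), 10L)
    # single level: mean equals the overall eigengene mean of zero
    meta1 <- data.frame(group = rep("all", 10), row.names = colnames(e))
    out1 <- summarizeEigengeneByCategory(eig, meta1, "group")
    expect_equal(out1$summary$mean, 0, tolerance = 1e-12)
    expect_error(summarizeEigengeneByCategory(eig, meta, "nope"), "unknown")
})

test_that("kME matches direct correlation and hubs rank by kME with tie rules", {
    sim <- simulateExpression(simulationDesign(30, c(15L, 15L),
                                               withinModuleCor = 0.7,
                                               seed = 63L))
    ds <- sim$dataset
    net <- buildNetwork(ds, power = 6)
    ms <- trueModuleSet(sim)
    eg <- computeEigengenes(ds, ms)
    mem <- moduleMembership(ds, eg, net, ms)
    # kME equals independent recomputation feature by feature
    m <- exprMatrix(ds)
    for (f in sample(colnames(m), 5)) {
        for (mod in c("1", "2")) {
            expect_equal(mem$kME[f, mod],
                         cor(m[, f], eigengenes(eg)[mod, ]),
                         tolerance = 1e-12)
        }
    }
    # intramodular connectivity equals the adjacency row sums within module
    adj <- adjacencyMatrix(net)
    f1 <- names(sim$trueLabels)[sim$trueLabels == 1L]
    expect_equal(unname(mem$intramodularConnectivity[f1[1]]),
                 sum(adj[f1[1], setdiff(f1, f1[1])]),
                 tolerance = 1e-12)

    hubs <- hubGenes(mem, ms, topN = 5)
    expect_equal(names(hubs), c("1", "2"))
    expect_equal(nrow(hubs[["1"]]), 5L)
    expect_true(all(diff(hubs[["1"]]$kME) <= 1e-15))
    # top hub has the maximum kME within its module
    expect_equal(hubs[["1"]]$kME[1], max(mem$kME[f1, "1"]))

    # module smaller than topN returns all members
    hubsAll <- hubGenes(mem, ms, topN = 100)
    expect_equal(nrow(hubsAll[["1"]]), 15L)
})

test_that("hub tie-break is lexicographic on equal kME and connectivity", {
    profile <- c(1, 5, 2, 8, 3, 9, 4, 7, 2, 6)
    m <- cbind(b = profile, a = profile, c = rev(profile))
    rownames(m) <- paste0("s", 1:10)
    ds <- CoexDataSet(m)
    labels <- stats::setNames(c(1L, 1L, 0L), colnames(m))
    ms <- trueModuleSet(labels)
    net <- buildNetwork(ds, power = 2)
    eg <- computeEigengenes(ds, ms)
    mem <- moduleMembership(ds, eg, net, ms)
    hubs <- hubGenes(mem, ms, topN = 2)
    expect_equal(hubs[["1"]]$feature, c("a", "b"))
})
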