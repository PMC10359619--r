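test_that("simulation is bit-reproducible from its seed", {
    des <- simulationDesign(20, c(10L, 10L), nBackground = 5L, seed = 99L)
    s1 <- simulateExpression(des)
    s2 <- simulateExpression(des)
    expect_identical(exprMatrix(s1$dataset), exprMatrix(s2$dataset))
    expect_identical(s1$trueLabels, s2$trueLabels)
    s3 <- simulateExpression(simulationDesign(20, c(10L, 10L),
                                              nBackground = 5L, seed = 100L))
    expect_false(identical(exprMatrix(s1$dataset), exprMatrix(s3$dataset)))
})

test_that("realized within-module correlation tracks the target rho", {
    for (rho in c(0.5, 0.7)) {
        devs <- vapply(1:20, function(s) {
            sim <- simulateExpression(simulationDesign(
                60, c(40L, 40L), withinModuleCor = rho, seed = 200L + s))
            m <- exprMatrix(sim$dataset)
            r <- cor(m[, sim$trueLabels == 1L])
            mean(r[upper.tri(r)]) - rho
        }, numeric(1))
        # mean realized correlation within 3 standard errors of the target
        expect_lt(abs(mean(devs)), 3 * sd(devs) / sqrt(length(devs)))
    }
    # near-1 target with weak noise gives very tight modules
    simHi <- simulateExpression(simulationDesign(50, 30L,
                                                 withinModuleCor = 0.97,
                                                 seed = 300L))
    r <- cor(exprMatrix(simHi$dataset))
    expect_gte(mean(r[upper.tri(r)]), 0.9)
})

test_that("background-only data show only sampling-noise correlations", {
    n <- 50
    sim <- simulateExpression(simulationDesign(n, integer(0),
                                               nBackground = 80L,
                                               seed = 301L))
    r <- cor(exprMatrix(sim$dataset))
    expect_lt(mean(abs(r[upper.tri(r)])), 2 / sqrt(n))
    expect_true(all(sim$trueLabels == 0L))
})

test_that("adjusted Rand index matches the pair-enumeration oracle", {
    ids <- paste0("g", 1:40)
    truth <- stats::setNames(rep(1:2, each = 20), ids)
    # perfect recovery
    expect_equal(evaluateRecovery(truth, truth)$ari, 1.0)
    # one giant module against two planted halves
    giant <- stats::setNames(rep(1L, 40), ids)
    expect_equal(adjustedRandIndex(truth, giant),
                 pairCountARI(truth, giant), tolerance = 1e-12)
    # randomized labelings across sizes
    set.seed(74)
    for (i in 1:10) {
        a <- sample(0:3, 30, replace = TRUE)
        b <- sample(0:3, 30, replace = TRUE)
        expect_equal(adjustedRandIndex(a, b), pairCountARI(a, b),
                     tolerance = 1e-12)
        expect_equal(adjustedRandIndex(a, b),
                     mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
    # random labels hover near zero on average
    set.seed(75)
    aris <- replicate(200, {
        a <- sample(1:3, 60, replace = TRUE)
        b <- sample(1:3, 60, replace = TRUE)
        adjustedRandIndex(a, b)
    })
    expect_lt(abs(mean(aris)), 0.02)
    expect_error(evaluateRecovery(truth, stats::setNames(1L, "other")),
                 "different features")
})

test_that("recovery report pairs each planted module with its best match", {
    ids <- paste0("g", 1:30)
    truth <- stats::setNames(rep(1:3, each = 10), ids)
    det <- stats::setNames(c(rep(2L, 10), rep(1L, 10), rep(0L, 10)), ids)
    rec <- evaluateRecovery(truth, det)
    pm <- rec$perModuleJaccard
    expect_equal(pm$bestMatch[pm$plantedModule == 1], 2L)
    expect_equal(pm$jaccard[pm$plantedModule == 1], 1)
    expect_equal(pm$jaccard[pm$plantedModule == 3], 0)
})

test_that("planted trait links surface as the module's top association", {
    hits <- 0L
    for (s in 1:10) {
        sim <- simulateExpression(simulationDesign(
            40, c(30L, 30L), withinModuleCor = 0.7, seed = 400L + s,
            traitLinks = data.frame(module = 1L, trait = "burden",
                                    effect = 0.8, type = "numeric")))
        meta <- as.data.frame(sampleData(sim$dataset))
        meta$decoy <- rnorm(40)
        eg <- computeEigengenes(sim$dataset, trueModuleSet(sim))
        res <- moduleTraitCorrelation(eg, meta)
        row <- res[res$module == "1", ]
        hits <- hits + (row$trait[which.min(row$padj)] == "burden")
    }
    expect_gte(hits, 9L)
})

test_that("binary trait links produce level-separated eigengene summaries", {
    sim <- simulateExpression(simulationDesign(
        60, c(30L,  30L), withinModuleCor = 0.8, seed = 88L,
        traitLinks = data.frame(module = 1L, trait = "genotype",
                                effect = 3, type = "binary")))
    meta <- as.data.frame(sampleData(sim$dataset))
    expect_true(is.factor(meta$genotype))
    eg <- computeEigengenes(sim$dataset, trueModuleSet(sim))
    out <- summarizeEigengeneByCategory(eg, meta, "genotype")
    s1 <- out$summary[out$summary$module == "1", ]
    expect_gt(abs(s1$mean[s1$level == "case"] -
                  s1$mean[s1$level == "control"]), 0.5)
})
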