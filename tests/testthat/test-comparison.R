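test_that("overlap statistics match direct counting", {
    res <- compareModuleSets(list(m1 = c("g1", "g2", "g3")),
                             list(x = c("g2", "g3", "g4")))
    expect_equal(res$nShared, 2)
    expect_equal(res$jaccard, 0.5)
    expect_equal(res$fractionOfA, 2 / 3)
    expect_equal(res$fractionOfB, 2 / 3)
    expect_equal(res$universeSize, 4)

    # identical sets
    idn <- compareModuleSets(list(a = c("g1", "g2")), list(b = c("g1", "g2")),
                             universe = paste0("g", 1:10))
    expect_equal(idn$jaccard, 1)
    expect_equal(idn$nShared, 2)

    # disjoint sets: zero-overlap tail covers everything
    dis <- compareModuleSets(list(a = c("g1", "g2")), list(b = c("g3", "g4")),
                             universe = paste0("g", 1:10))
    expect_equal(dis$jaccard, 0)
    expect_gte(dis$fisherP, hyperTailOracle(0, 2, 2, 10) - 1e-12)
    expect_equal(dis$fisherP, 1)
})

test_that("fisher p equals the exhaustive hypergeometric tail", {
    expect_equal(fisherOverlapP(10, 20, 20, 100),
                 hyperTailOracle(10, 20, 20, 100), tolerance = 1e-14)
    set.seed(71)
    for (i in 1:50) {
        N <- sample(10:60, 1)
        ka <- sample(1:N, 1); kb <- sample(1:N, 1)
        ks <- max(0, ka + kb - N):min(ka, kb)
        k <- ks[sample.int(length(ks), 1)]
        expect_equal(fisherOverlapP(k, ka, kb, N),
                     hyperTailOracle(k, ka, kb, N), tolerance = 1e-12)
    }
    # two-sided option agrees with fisher.test
    tab <- matrix(c(10, 10, 10, 70), 2)
    expect_equal(fisherOverlapP(10, 20, 20, 100, alternative = "two.sided"),
                 fisher.test(tab)$p.value)
})

test_that("jaccard identity and symmetry hold on randomized sets", {
    set.seed(72)
    uni <- paste0("g", 1:200)
    for (i in 1:20) {
        A <- list(a = sample(uni, sample(5:60, 1)))
        B <- list(b = sample(uni, sample(5:60, 1)))
        ab <- compareModuleSets(A, B, universe = uni)
        ba <- compareModuleSets(B, A, universe = uni)
        expect_equal(ab$jaccard,
                     ab$nShared / (ab$sizeA + ab$sizeB - ab$nShared))
        expect_lte(ab$jaccard, min(ab$fractionOfA, ab$fractionOfB) + 1e-15)
        expect_equal(ab$jaccard, ba$jaccard)
        expect_equal(ab$fisherP, ba$fisherP)
        expect_equal(ab$fractionOfA, ba$fractionOfB)
    }
})

test_that("one-sided overlap p-values are not anti-conservative under the null", {
    set.seed(73)
    uni <- paste0("g", 1:100)
    ps <- replicate(400, {
        A <- sample(uni, 20); B <- sample(uni, 20)
        fisherOverlapP(length(intersect(A, B)), 20, 20, 100)
    })
    for (alpha in c(0.05, 0.1, 0.25))
        expect_lte(mean(ps <= alpha), alpha + 2.5 * sqrt(alpha * (1 - alpha) / 400))
})

test_that("marker-list comparison runs per pair with one BH family", {
    sets <- list(m1 = paste0("g", 1:10), m2 = paste0("g", 11:20),
                 m3 = paste0("g", 21:30))
    markers <- list(typeA = paste0("g", 1:10), typeB = paste0("g", 31:40))
    res <- compareToMarkerLists(sets, markers)
    expect_equal(nrow(res), 6L)
    expect_equal(res$jaccard[res$moduleA == "m1" & res$moduleB == "typeA"], 1)
    expect_true(all(res$jaccard[res$moduleB == "typeB"] == 0))
    expect_equal(res$fisherPAdjusted,
                 p.adjust(res$fisherP, "BH"))
})

test_that("universe handling drops alien genes and rejects dead sets", {
    expect_warning(
        res <- compareModuleSets(list(a = c("g1", "g2", "zz")),
                                 list(b = c("g2", "g3")),
                                 universe = paste0("g", 1:5)),
        "outside the universe")
    expect_equal(res$sizeA, 2)
    expect_error(suppressWarnings(
        compareModuleSets(list(a = c("zz")), list(b = c("g1")),
                          universe = paste0("g", 1:5))),
        "disjoint")
    expect_error(compareModuleSets(list(a = character(0)),
                                   list(b = "g1")), "empty")
    inter <- suppressWarnings(
        compareModuleSets(list(a = c("g1", "g2")), list(b = c("g2", "g3")),
                          universe = "intersection"))
    expect_equal(inter$universeSize, 1)
})

test_that("comparison filter is strict on jaccard and inclusive on adjusted p", {
    res <- data.frame(moduleA = c("a", "b", "c"), moduleB = c("x", "y", "z"),
                      jaccard = c(0.05, 0.051, 0.5),
                      fisherPAdjusted = c(0.01, 0.05, 0.2))
    kept <- filterComparison(res, minJaccard = 0.05, maxAdjustedP = 0.05)
    expect_equal(kept$moduleA, "b")   # 0.05 dropped (strict >), 0.2 over alpha
    all_ <- filterComparison(res, minJaccard = 0, maxAdjustedP = 1)
    expect_equal(nrow(all_), 3L)
})
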