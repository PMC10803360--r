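test_that("amplification rates are plain call fractions", {
    calls <- matrix(NA_integer_, 3, 40,
                    dimnames = list(c("a", "b", "c"), sprintf("L%02d", 1:40)))
    calls["a", 1:36] <- 1L
    calls["b", ] <- 0L
    gm <- GenotypeMatrix(calls)
    r <- amplificationRates(gm)
    expect_equal(unname(r$sample["a"]), 0.90)
    expect_equal(unname(r$sample["c"]), 0)
    expect_equal(r$failed, "c")
    expect_equal(unname(r$locus["L01"]), 2 / 3)
})

test_that("cleaning reaches the hand-traced fixed point", {
    # 10 samples x 20 loci. Loci L18-L20 are bad (missing for s1-s5);
    # dropping them lifts s1 and s2 (0.85 raw) back over the 0.9 sample
    # threshold, while s3 stays poor on the good loci and is removed.
    calls <- matrix(1L, 10, 20,
                    dimnames = list(paste0("s", 1:10),
                                    sprintf("L%02d", 1:20)))
    calls[paste0("s", 1:5), c("L18", "L19", "L20")] <- NA  # rate 0.5 loci
    calls["s3", sprintf("L%02d", 1:8)] <- NA               # 9/17 after drop
    res <- cleanMatrix(GenotypeMatrix(calls), sampleMin = 0.9,
                       locusMin = 0.8)
    expect_setequal(sampleIds(res$genotypes), paste0("s", c(1:2, 4:10)))
    expect_false(any(c("L18", "L19", "L20") %in% locusIds(res$genotypes)))
    expect_true(all(c("L18", "s3") %in% res$log$id))
    # an already-clean matrix is a fixed point
    again <- cleanMatrix(res$genotypes, 0.9, 0.8)
    expect_identical(genotypeCalls(again$genotypes),
                     genotypeCalls(res$genotypes))
    expect_equal(nrow(again$log), 0L)
})

test_that("failed samples are dropped before rate filtering", {
    calls <- matrix(1L, 3, 5,
                    dimnames = list(paste0("s", 1:3), paste0("L", 1:5)))
    calls["s3", ] <- NA
    res <- cleanMatrix(GenotypeMatrix(calls))
    expect_equal(res$failed, "s3")
    expect_equal(res$log$type[res$log$id == "s3"], "failed_sample")
})

test_that("pairwise mismatches count allele differences on shared loci", {
    calls <- rbind(a = c(0L, 1L, 2L), b = c(0L, 2L, 2L),
                   c = c(0L, NA, 1L), d = c(2L, 0L, 1L))
    colnames(calls) <- paste0("L", 1:3)
    mm <- pairwiseMismatches(GenotypeMatrix(calls))
    expect_equal(mismatchCounts(mm)["a", "b"], 1)      # het vs hom-alt
    expect_equal(lociCompared(mm)["a", "b"], 3L)
    expect_equal(mismatchCounts(mm)["c", "d"], 2)      # opposite homs
    expect_equal(lociCompared(mm)["c", "d"], 2L)       # missing excluded
    expect_equal(mismatchCounts(mm)["a", "a"], 0)
})

test_that("mismatch matrices are symmetric with zero diagonal", {
    for (seed in 1:5) {
        set.seed(seed)
        gm <- hweMatrix(12, runif(20, 0.3, 0.5), missing = 0.2)
        mm <- pairwiseMismatches(gm)
        M <- mismatchCounts(mm)
        expect_true(isSymmetric(unname(M)))
        expect_true(all(diag(M) == 0))
        expect_true(all(M[!mm@noOverlap] <=
                        2 * lociCompared(mm)[!mm@noOverlap]))
    }
})

test_that("pairs sharing no locus get maximal dissimilarity and a flag", {
    calls <- rbind(a = c(1L, NA), b = c(NA, 1L), c = c(1L, 1L))
    colnames(calls) <- c("L1", "L2")
    mm <- pairwiseMismatches(GenotypeMatrix(calls))
    expect_true(mm@noOverlap["a", "b"])
    expect_equal(mismatchCounts(mm)["a", "b"], 4)   # 2 x locus count
})

test_that("average linkage reproduces hand-computed merges", {
    D <- matrix(c(0, 0, 4,
                  0, 0, 4,
                  4, 4, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    tree <- upgmaTree(D)
    expect_equal(tree$height, c(0, 4))
    # four equidistant leaves merge at the tied height throughout
    D2 <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    diag(D2) <- 0
    expect_equal(upgmaTree(D2)$height, c(2, 2, 2))
})

test_that("upgma agrees with a brute-force recomputation oracle", {
    for (seed in 1:40) {
        set.seed(seed)
        n <- sample(4:7, 1)
        D <- matrix(sample(0:12, n * n, replace = TRUE), n)
        D <- D + t(D); diag(D) <- 0
        dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
        tree <- upgmaTree(D)
        expect_equal(tree$height, bruteUpgmaHeights(D), tolerance = 1e-9)
        expect_true(all(diff(tree$height) >= -1e-9))
    }
})

test_that("upgma matches stats::hclust on tie-free matrices", {
    for (seed in 1:10) {
        set.seed(seed)
        n <- 8
        D <- matrix(runif(n * n, 1, 30), n)
        D <- D + t(D); diag(D) <- 0
        dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
        ours <- upgmaTree(D)
        ref <- stats::hclust(stats::as.dist(D), method = "average")
        expect_equal(ours$height, ref$height, tolerance = 1e-9)
        for (h in stats::quantile(ref$height, c(0.25, 0.75))) {
            ga <- cutGroups(ours, h)
            expect_equal(sort(as.integer(table(groupMembership(ga)))),
                         sort(as.integer(table(stats::cutree(ref, h = h)))))
        }
    }
})

test_that("cut height separates scats exactly at the mismatch threshold", {
    calls <- rbind(a = rep(1L, 10), b = rep(1L, 10), c = rep(1L, 10),
                   d = rep(0L, 10))
    calls["b", 1] <- 0L                      # b differs from a by one allele
    calls["c", 1:2] <- 0L                    # c differs from a by two
    colnames(calls) <- paste0("L", 1:10)
    gm <- GenotypeMatrix(calls)
    tree <- upgmaTree(pairwiseMismatches(gm))
    g1 <- groupMembership(cutGroups(tree, 1))
    expect_equal(g1[["a"]], g1[["b"]])       # <= 1 mismatch: same bat
    expect_false(g1[["a"]] == g1[["c"]])     # 2 mismatches: different
    # h = 0 keeps exactly the distinct observed genotypes apart
    g0 <- groupMembership(cutGroups(tree, 0))
    expect_equal(length(unique(g0)), nrow(unique(calls)))
})

test_that("group counts fall monotonically along the elbow curve", {
    set.seed(12)
    gm <- hweMatrix(15, runif(25, 0.3, 0.5))
    tree <- upgmaTree(pairwiseMismatches(gm))
    ec <- elbowCurve(tree, ceiling(max(tree$height)) + 2)
    expect_true(all(diff(ec$n_groups) <= 0))
    expect_equal(ec$n_groups[1], nrow(unique(genotypeCalls(gm))))
    expect_equal(ec$n_groups[nrow(ec)], 1L)          # beyond tallest merge
    expect_equal(length(groupSizes(cutGroups(tree, Inf))), 1L)
})

test_that("representatives are the best-amplifying group members", {
    calls <- rbind(s1 = c(1L, 1L, NA, NA), s2 = c(1L, 1L, 1L, NA),
                   s3 = c(1L, 1L, 1L, 1L))
    colnames(calls) <- paste0("L", 1:4)
    gm <- GenotypeMatrix(calls)
    tree <- upgmaTree(pairwiseMismatches(gm))
    ga <- cutGroups(tree, 0, gm)
    expect_equal(unname(representatives(ga)), "s3")
})

test_that("heat map ordering permutes rows to leaf order symmetrically", {
    set.seed(3)
    gm <- hweMatrix(8, runif(12, 0.3, 0.5))
    mm <- pairwiseMismatches(gm)
    tree <- upgmaTree(mm)
    hm <- heatmapOrder(mm, tree)
    expect_equal(rownames(hm$matrix), tree$labels[tree$order])
    expect_true(isSymmetric(unname(hm$matrix)))
    expect_equal(nrow(hm$table), 64L)
})
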