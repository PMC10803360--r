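test_that("identical configs reproduce identical studies", {
    cfg <- simulationConfig(seed = 8, nIndividuals = 10,
                            scatsPerIndividual = 4)
    a <- simulateScats(simulateTruth(cfg), cfg)
    b <- simulateScats(simulateTruth(cfg), cfg)
    expect_identical(genotypeCalls(a$genotypes), genotypeCalls(b$genotypes))
    expect_identical(a$rfu, b$rfu)
    expect_error(simulationConfig(), "seed")
    expect_error(simulationConfig(seed = 1, dyads = c(twin = 3)), "unknown")
})

test_that("pedigreed dyads obey Mendelian allele sharing", {
    cfg <- simulationConfig(seed = 14, nLoci = 60, nIndividuals = 0,
                            dyads = c(parent_offspring = 50, clone = 10),
                            scatsPerIndividual = 1)
    tr <- simulateTruth(cfg)
    dy <- truthDyads(tr)
    G <- trueGenotypes(tr)
    po <- dy[dy$type == "parent_offspring", ]
    for (k in seq_len(nrow(po))) {
        # a parent and its offspring can never be opposite homozygotes
        expect_false(any(abs(G[po$id1[k], ] - G[po$id2[k], ]) == 2L))
    }
    cl <- dy[dy$type == "clone", ]
    for (k in seq_len(nrow(cl)))
        expect_identical(G[cl$id1[k], ], G[cl$id2[k], ])
})

test_that("realized allele frequencies match the drawn values", {
    cfg <- simulationConfig(seed = 6, nLoci = 30, nIndividuals = 4000,
                            scatsPerIndividual = 1)
    tr <- simulateTruth(cfg)
    p <- trueAlleleFreqs(tr)
    phat <- colMeans(trueGenotypes(tr)) / 2
    se <- sqrt(p * (1 - p) / (2 * 4000))
    expect_true(all(abs(phat - p) < 4 * se))
    expect_true(all(p >= 0.3 & p <= 0.5))
})

test_that("the noiseless limit copies truth exactly", {
    cfg <- simulationConfig(seed = 3, nIndividuals = 8,
                            scatsPerIndividual = 3, missingProb = 0,
                            adoRate = 0, replicateFraction = 0)
    tr <- simulateTruth(cfg)
    sim <- simulateScats(tr, cfg)
    g <- genotypeCalls(sim$genotypes)
    owner <- sampleMeta(sim$genotypes)$individual_id
    expect_false(anyNA(g))
    for (i in seq_len(nrow(g)))
        expect_identical(unname(g[i, ]), unname(trueGenotypes(tr)[owner[i], ]))
})

test_that("missingness is calibrated to the configured probability", {
    cfg <- simulationConfig(seed = 10, nLoci = 100, nIndividuals = 50,
                            scatsPerIndividual = 2, missingProb = 0.2,
                            adoRate = 0, replicateFraction = 0)
    sim <- simulateScats(simulateTruth(cfg), cfg)
    frac <- mean(is.na(genotypeCalls(sim$genotypes)))
    se <- sqrt(0.2 * 0.8 / (100 * 100))
    expect_lt(abs(frac - 0.2), 4 * se)
})

test_that("dropout strikes only heterozygous truth loci", {
    cfg <- simulationConfig(seed = 19, nIndividuals = 30,
                            scatsPerIndividual = 4, missingProb = 0.05,
                            adoRate = 0.2, replicateFraction = 0)
    tr <- simulateTruth(cfg)
    sim <- simulateScats(tr, cfg)
    g <- genotypeCalls(sim$genotypes)
    G <- trueGenotypes(tr)[sampleMeta(sim$genotypes)$individual_id, ]
    changed <- !is.na(g) & g != G
    # every change starts from a true heterozygote and lands on a homozygote
    expect_true(all(G[changed] == 1L))
    expect_true(all(g[changed] != 1L))
})

test_that("false alleles convert homozygotes at the configured rate", {
    cfg <- simulationConfig(seed = 20, nLoci = 200, nIndividuals = 50,
                            scatsPerIndividual = 2, missingProb = 0,
                            adoRate = 0, falseAlleleRate = 0.1,
                            replicateFraction = 0)
    tr <- simulateTruth(cfg)
    sim <- simulateScats(tr, cfg)
    g <- genotypeCalls(sim$genotypes)
    G <- trueGenotypes(tr)[sampleMeta(sim$genotypes)$individual_id, ]
    hom <- G != 1L
    rate <- mean(g[hom] == 1L)
    expect_lt(abs(rate - 0.1), 4 * sqrt(0.1 * 0.9 / sum(hom)))
    expect_true(all(g[!hom] == 1L))   # hets untouched when ado = 0
})

test_that("within-individual mismatches match the dropout error budget", {
    eps <- 0.025
    cfg <- simulationConfig(seed = 44, nLoci = 47, nIndividuals = 300,
                            scatsPerIndividual = rep(2, 300),
                            missingProb = 0, adoRate = eps,
                            replicateFraction = 0)
    tr <- simulateTruth(cfg)
    sim <- simulateScats(tr, cfg)
    mm <- mismatchCounts(pairwiseMismatches(sim$genotypes))
    meta <- sampleMeta(sim$genotypes)
    within <- vapply(rownames(trueGenotypes(tr)), function(ind) {
        sc <- meta$sample_id[meta$individual_id == ind]
        mm[sc[1], sc[2]]
    }, numeric(1))
    # analytic expectation: only het loci can drop; per het locus the
    # pair differs by 2h(1-h) * 1 + h^2 * 1 with h = eps/(2 - eps)
    h <- eps / (2 - eps)
    nHet <- rowSums(trueGenotypes(tr) == 1L)
    expectM <- mean(nHet) * (2 * h - h^2)
    mcse <- sd(within) / sqrt(length(within))
    expect_lt(abs(mean(within) - expectM), 3 * mcse)
    # the printed eps x L budget is a (conservative) upper bound
    expect_lt(mean(within), errorBudget(eps, 47))
})

test_that("replicates share their original scat's DNA quality", {
    cfg <- simulationConfig(seed = 12, nIndividuals = 15,
                            scatsPerIndividual = 3, replicateFraction = 0.3)
    sim <- simulateScats(simulateTruth(cfg), cfg)
    meta <- sampleMeta(sim$genotypes)
    ro <- replicateOf(sim$genotypes)
    expect_gt(length(ro), 0L)
    expect_equal(meta[names(ro), "missing_prob"], meta[ro, "missing_prob"])
    expect_equal(meta[names(ro), "individual_id"], meta[ro, "individual_id"])
})
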