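test_that("step 1 recovers the simulated individuals and is deterministic", {
    recovered <- vapply(1:10, function(s) {
        cfg <- simulationConfig(seed = s, nIndividuals = 20,
                                scatsPerIndividual = 5, missingProb = 0.05,
                                adoRate = 0.003, replicateFraction = 0.1)
        sim <- simulateScats(simulateTruth(cfg), cfg)
        s1 <- runStepOne(sim$genotypes)
        s1$nIndividuals == individualsPresent(s1$cleaned)
    }, logical(1))
    expect_gte(sum(recovered), 8)

    cfg <- simulationConfig(seed = 2, nIndividuals = 10,
                            scatsPerIndividual = 4)
    sim <- simulateScats(simulateTruth(cfg), cfg)
    a <- runStepOne(sim$genotypes)
    b <- runStepOne(sim$genotypes)
    expect_identical(groupMembership(a$groups), groupMembership(b$groups))
    expect_identical(a$elbow, b$elbow)
})

test_that("failed samples are reported apart from rate-filtered ones", {
    cfg <- simulationConfig(seed = 4, nIndividuals = 8,
                            scatsPerIndividual = 4, missingProb = 0.05,
                            adoRate = 0.003, replicateFraction = 0)
    sim <- simulateScats(simulateTruth(cfg), cfg)
    g <- genotypeCalls(sim$genotypes)
    g["S0001", ] <- NA
    s1 <- runStepOne(GenotypeMatrix(g, sampleMeta = sampleMeta(sim$genotypes)))
    expect_equal(s1$failed, "S0001")
    expect_false("S0001" %in% names(groupMembership(s1$groups)))
    # every input sample is failed, filtered out, or grouped
    log <- s1$cleanLog
    accounted <- union(names(groupMembership(s1$groups)),
                       union(log$id[log$type != "locus"], s1$failed))
    expect_setequal(accounted, rownames(g))
})

test_that("consensus genotypes take the group majority, ties go missing", {
    calls <- rbind(a1 = c(0L, 1L, 1L, NA), a2 = c(0L, 1L, 2L, NA),
                   a3 = c(0L, NA, 1L, NA), b1 = c(2L, 2L, 2L, 1L))
    colnames(calls) <- paste0("L", 1:4)
    gm <- GenotypeMatrix(calls)
    tree <- upgmaTree(pairwiseMismatches(gm))
    ga <- cutGroups(tree, 2, gm)
    cons <- consensusGenotypes(gm, ga)
    expect_equal(nrow(cons), 2L)
    gA <- genotypeCalls(cons)[1, ]
    expect_equal(unname(gA), c(0L, 1L, 1L, NA))
    meta <- sampleMeta(cons)
    expect_equal(meta$n_scats, c(3L, 1L))
    # a genuine 1-1 tie stays missing
    tied <- rbind(x1 = c(0L, 1L), x2 = c(0L, 2L))
    colnames(tied) <- c("L1", "L2")
    gmT <- GenotypeMatrix(tied)
    gaT <- cutGroups(upgmaTree(pairwiseMismatches(gmT)), 5, gmT)
    expect_true(is.na(genotypeCalls(consensusGenotypes(gmT, gaT))[1, "L2"]))
})

test_that("step 2 unions panel loci after the amplification filter", {
    cfg <- simulationConfig(seed = 9, nLoci = 40, nIndividuals = 12,
                            scatsPerIndividual = 4, missingProb = 0.03,
                            adoRate = 0.003, replicateFraction = 0)
    tr <- simulateTruth(cfg)
    sim <- simulateScats(tr, cfg)
    s1 <- runStepOne(sim$genotypes)
    reps <- unname(representatives(s1$groups))
    # extended panels: 30 loci genotyped on the representative scats,
    # five of them failing the 50% amplification floor
    set.seed(99)
    p2 <- matrix(stats::rbinom(length(reps) * 30, 2, 0.4),
                 nrow = length(reps),
                 dimnames = list(reps, sprintf("P2_%02d", 1:30)))
    p2[, 1:5] <- NA
    s2 <- runStepTwo(s1, panel23 = GenotypeMatrix(p2), rfu = sim$rfu)
    expect_length(s2$lociStep2, 25L)
    expect_equal(sort(locusIds(s2$consensus)),
                 sort(c(s2$lociStep1, s2$lociStep2)))
    expect_false(anyDuplicated(locusIds(s2$consensus)) > 0)
    expect_true(all(s2$sex$category %in%
                    c("male", "female", "likely_male", "likely_female",
                      "undetermined")))
    expect_true(is.list(s2$relatedness))
})

test_that("a configured project runs end to end from files", {
    dir <- withr::local_tempdir()
    cfg <- simulationConfig(seed = 21, nLoci = 25, nIndividuals = 8,
                            scatsPerIndividual = 4, missingProb = 0.03,
                            adoRate = 0.003, replicateFraction = 0.1)
    tr <- simulateTruth(cfg)
    sim <- simulateScats(tr, cfg)
    gPath <- file.path(dir, "panel1.csv")
    writeGenotypeTable(sim$genotypes, gPath)
    rPath <- file.path(dir, "rfu.csv")
    utils::write.csv(sim$rfu, rPath, row.names = FALSE)
    ro <- replicateOf(sim$genotypes)
    repPath <- file.path(dir, "replicates.csv")
    utils::write.csv(data.frame(replicate = names(ro), original = ro),
                     repPath, row.names = FALSE)
    meta <- passingMetadata(sim$genotypes, seed = 1)
    mPath <- file.path(dir, "meta.csv")
    utils::write.csv(meta, mPath, row.names = FALSE)
    yml <- file.path(dir, "project.yaml")
    writeLines(c(paste0("panel1_genotypes: ", gPath),
                 paste0("rfu: ", rPath),
                 paste0("replicates: ", repPath),
                 paste0("metadata: ", mPath)), yml)
    out <- file.path(dir, "results")
    res <- runProject(yml, outDir = out)
    expect_s4_class(res$step2$consensus, "GenotypeMatrix")
    expect_true(file.exists(file.path(out, "groups.csv")))
    expect_true(file.exists(file.path(out, "consensus.vcf")))
    expect_true(file.exists(file.path(out, "provenance.txt")))
    # the file round trip must not change the identification outcome:
    # truth lives in the simulation metadata, keyed by sample id
    present <- length(unique(
        sampleMeta(sim$genotypes)[sampleIds(res$step1$cleaned),
                                  "individual_id"]))
    expect_equal(res$step1$nIndividuals, present)
})
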