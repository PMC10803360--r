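# engineered 10-locus table: one failure for each of the first five
# steps (the two-SNP clone removes both its loci at step 1)
cascadeFixture <- function(seed = 101) {
    set.seed(seed)
    gm <- hweMatrix(40, rep(0.4, 10), prefix = "ind")
    meta <- passingMetadata(gm)
    meta$clone_id[1:2] <- "Cdup"            # step 1: clone with 2 SNPs
    meta$snp_count_in_clone[1:2] <- 2
    meta$tag_sequence[3] <- randomTag(45)   # step 2: short tag
    meta$snp_position[4] <- 50              # step 3: SNP too close to end
    meta$tag_sequence[4] <- randomTag(69)
    meta$mean_depth_alt[5] <- 280           # step 4: depth 300 > 200
    meta$call_rate[6] <- 0.5                # step 5: poor locus call rate
    # keep the metadata informative for the later steps
    meta$het_obs <- pmin(pmax(meta$het_obs, 0.3), 0.5)
    meta$maf <- pmin(pmax(meta$maf, 0.32), 0.48)
    list(gm = gm, meta = meta)
}

test_that("each early filter removes exactly its engineered locus", {
    fx <- cascadeFixture()
    rep <- applyFilterCascade(fx$meta, fx$gm)
    st <- filterSteps(rep)
    expect_equal(st$loci[st$step == "raw"], 10)
    expect_equal(st$loci[st$step == "single SNP per tag"], 8)
    expect_equal(st$loci[st$step == "tag length"], 7)
    expect_equal(st$loci[st$step == "SNP position"], 6)
    expect_equal(st$loci[st$step == "read depth"], 5)
    expect_equal(st$loci[st$step == "locus call rate"], 4)
    expect_setequal(retainedLoci(rep),
                    c("L007", "L008", "L009", "L010"))
    expect_equal(length(retainedIndividuals(rep)), 40)
})

test_that("attrition is monotone and the cascade is idempotent", {
    for (seed in c(5, 17, 42)) {
        set.seed(seed)
        # complete calls: with missing data an individual sitting exactly
        # at the call-rate floor can flip once the locus set shrinks, so
        # strict idempotence is a complete-data property
        gm <- hweMatrix(40, runif(30, 0.3, 0.5))
        meta <- passingMetadata(gm)
        # rough the metadata up a little
        meta$call_rate[sample(30, 3)] <- 0.5
        meta$reproducibility[sample(30, 2)] <- 0.9
        meta$maf[sample(30, 2)] <- 0.1
        rep1 <- applyFilterCascade(meta, gm)
        st <- filterSteps(rep1)
        expect_true(all(diff(st$loci) <= 0))
        expect_true(all(diff(st$individuals) <= 0))
        # applying the cascade to its own survivors changes nothing
        if (length(retainedLoci(rep1)) >= 2) {
            gm2 <- gm[retainedIndividuals(rep1), retainedLoci(rep1)]
            meta2 <- meta[meta$locus_id %in% retainedLoci(rep1), ]
            rep2 <- applyFilterCascade(meta2, gm2)
            expect_setequal(retainedLoci(rep2), retainedLoci(rep1))
            expect_setequal(retainedIndividuals(rep2),
                            retainedIndividuals(rep1))
        }
    }
    # monotonicity also holds with missing calls in play
    set.seed(7)
    gmM <- hweMatrix(40, runif(30, 0.3, 0.5), missing = 0.05)
    stM <- filterSteps(applyFilterCascade(passingMetadata(gmM), gmM))
    expect_true(all(diff(stM$loci) <= 0))
    expect_true(all(diff(stM$individuals) <= 0))
})

test_that("an individual below the call-rate floor is dropped at step 6", {
    set.seed(9)
    gm <- hweMatrix(5, rep(0.4, 10), prefix = "ind")
    g <- genotypeCalls(gm)
    g["ind001", 1:5] <- NA                 # 50% call rate
    gm <- GenotypeMatrix(g)
    meta <- passingMetadata(gm)
    meta$call_rate <- 0.9                  # keep the locus filter quiet
    rep <- applyFilterCascade(meta, gm)
    expect_false("ind001" %in% retainedIndividuals(rep))
    st <- filterSteps(rep)
    expect_equal(st$individuals[st$step == "individual call rate"], 4)
})

test_that("paralogous tags are removed by sequence similarity", {
    set.seed(21)
    gm <- hweMatrix(8, rep(0.4, 3))
    meta <- passingMetadata(gm)
    # second tag nearly identical to the first (distance << 0.25)
    tag <- meta$tag_sequence[1]
    mutated <- tag
    substr(mutated, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                     substr(tag, 3, 3))[1]
    meta$tag_sequence[2] <- mutated
    rep <- applyFilterCascade(meta, gm)
    expect_false("L002" %in% retainedLoci(rep))
    expect_true("L001" %in% retainedLoci(rep))
})

test_that("equilibrium loci survive the Hardy-Weinberg filter", {
    # genotypes drawn in HWE should essentially never be rejected; note
    # the heterozygosity and MAF windows themselves do trim loci whose
    # true values sit at a window boundary (expected Ho equals the 0.5
    # ceiling whenever MAF is 0.5), which is sampling, not a defect
    set.seed(33)
    p <- runif(120, 0.32, 0.48)
    gm <- hweMatrix(200, p)
    meta <- passingMetadata(gm)
    rep <- applyFilterCascade(meta, gm)
    st <- filterSteps(rep)
    before <- st$loci[st$step == "minor allele frequency"]
    after <- st$loci[st$step == "Hardy-Weinberg equilibrium"]
    expect_gte(after / before, 0.95)
    # and a strong heterozygote deficit is caught even under Bonferroni
    set.seed(34)
    g <- genotypeCalls(hweMatrix(200, rep(0.4, 20)))
    het <- which(g == 1L)
    flip <- het[stats::runif(length(het)) < 0.7]
    g[flip] <- 2L * stats::rbinom(length(flip), 1, 0.5)
    pv <- vapply(seq_len(ncol(g)), function(j)
        hweExactTest(sum(g[, j] == 0), sum(g[, j] == 1), sum(g[, j] == 2)),
        numeric(1))
    expect_gt(mean(pv < 0.05 / 20), 0.9)
})
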