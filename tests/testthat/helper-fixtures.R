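# Shared fixtures and independent oracles, all built in code.

# random biallelic tag sequence
randomTag <- function(len = 69) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# HWE genotype matrix at given alternative-allele frequencies
hweMatrix <- function(n, p, missing = 0, prefix = "s") {
    L <- length(p)
    m <- t(matrix(stats::rbinom(L * n, 2L, p), nrow = L))
    if (missing > 0) m[stats::runif(length(m)) < missing] <- NA_integer_
    dimnames(m) <- list(sprintf("%s%03d", prefix, seq_len(n)),
                        sprintf("L%03d", seq_len(L)))
    GenotypeMatrix(m)
}

# metadata that passes every cascade filter, derived from genotypes
passingMetadata <- function(gm, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    loci <- locusIds(gm)
    g <- genotypeCalls(gm)
    n <- colSums(!is.na(g))
    p <- colSums(g, na.rm = TRUE) / (2 * pmax(n, 1))
    data.frame(locus_id = loci,
               clone_id = paste0("C", seq_along(loci)),
               snp_count_in_clone = 1,
               tag_sequence = vapply(loci, function(i) randomTag(69),
                                     character(1)),
               snp_position = 30,
               ref_allele = "C", alt_allele = "T",
               mean_depth_ref = 20, mean_depth_alt = 20,
               call_rate = colMeans(!is.na(g)),
               reproducibility = 0.99,
               het_obs = colMeans(g == 1L, na.rm = TRUE),
               maf = pmin(p, 1 - p))
}

# brute-force average-linkage oracle: recomputes every cluster-pair mean
# from the raw matrix at each step (no Lance-Williams update)
bruteUpgmaHeights <- function(D) {
    clusters <- as.list(seq_len(nrow(D)))
    heights <- numeric(0)
    while (length(clusters) > 1L) {
        best <- Inf; bi <- bj <- 0L
        for (i in seq_along(clusters)) {
            for (j in seq_along(clusters)) {
                if (i >= j) next
                d <- mean(D[clusters[[i]], clusters[[j]]])
                if (d < best - 1e-9) { best <- d; bi <- i; bj <- j }
            }
        }
        heights <- c(heights, best)
        clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
        clusters[[bj]] <- NULL
    }
    heights
}

# exhaustive Levene oracle: enumerate all placements of nA reference
# alleles over 2n slots paired as (1,2), (3,4), ...; every placement is
# equally likely conditional on the allele counts
leveneOracle <- function(n, nA) {
    slots <- 2L * n
    combos <- utils::combn(slots, nA)
    odd <- seq(1L, slots, by = 2L)
    hets <- apply(combos, 2L, function(idx) {
        isA <- logical(slots)
        isA[idx] <- TRUE
        sum(isA[odd] != isA[odd + 1L])
    })
    tab <- table(hets) / ncol(combos)
    list(het = as.integer(names(tab)), prob = as.numeric(tab))
}

# p-value from an enumerated Levene distribution
leveneOracleP <- function(dist, hObs) {
    pObs <- dist$prob[dist$het == hObs]
    sum(dist$prob[dist$prob <= pObs * (1 + 1e-9)])
}

# count groups implied by truth among the samples of a cleaned matrix
individualsPresent <- function(cleaned) {
    length(unique(sampleMeta(cleaned)[sampleIds(cleaned), "individual_id"]))
}
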