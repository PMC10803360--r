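#' Configuration of the SNP panel filter cascade
#'
#' Defaults reproduce the selection rules used to whittle a DArT-style
#' discovery set down to array-ready loci: single-SNP tags, adequate tag
#' length and interior SNP position (room for primer design), moderate
#' read depth, high call rate for loci and individuals, balanced allele
#' read depths, reproducibility in technical replicates, paralog removal
#' by tag-sequence similarity, informative heterozygosity and minor allele
#' frequency, Hardy-Weinberg equilibrium and linkage-equilibrium pruning.
#'
#' @param minTagLength minimum tag length in bp (default 50).
#' @param snpPositionRange allowed 1-based SNP offset in the tag
#'   (default c(25, 45)).
#' @param depthRange allowed mean total read depth (default c(5, 200)).
#' @param minLocusCallRate minimum per-locus genotyping rate (default 0.8).
#' @param minIndividualCallRate minimum per-individual genotyping rate
#'   (default 0.8); individuals below it are dropped.
#' @param alleleDepthRatioRange allowed alt/(ref+alt) mean-depth fraction
#'   (default c(0.2, 0.8)).
#' @param minReproducibility strict lower bound on reproducibility
#'   (default 0.95; loci must exceed it).
#' @param paralogHammingThreshold loci whose normalized tag Hamming
#'   distance to an earlier locus falls below this are treated as putative
#'   paralogs and removed (default 0.25).
#' @param hetRange allowed observed heterozygosity (default c(0.2, 0.5)).
#' @param mafRange allowed minor allele frequency (default c(0.3, 0.5)).
#' @param hweAlpha significance level of the exact HWE test (default 0.05).
#' @param hweCorrection multiple-testing correction, "bonferroni" or
#'   "none".
#' @param ldR2Max r-squared ceiling for LD pruning (default 0.2).
#' @return a list with class \code{filterConfig}.
#' @export
filterConfig <- function(minTagLength = 50,
                         snpPositionRange = c(25, 45),
                         depthRange = c(5, 200),
                         minLocusCallRate = 0.80,
                         minIndividualCallRate = 0.80,
                         alleleDepthRatioRange = c(0.2, 0.8),
                         minReproducibility = 0.95,
                         paralogHammingThreshold = 0.25,
                         hetRange = c(0.2, 0.5),
                         mafRange = c(0.3, 0.5),
                         hweAlpha = 0.05,
                         hweCorrection = c("bonferroni", "none"),
                         ldR2Max = 0.2) {
    hweCorrection <- match.arg(hweCorrection)
    cfg <- list(minTagLength = minTagLength,
                snpPositionRange = snpPositionRange,
                depthRange = depthRange,
                minLocusCallRate = minLocusCallRate,
                minIndividualCallRate = minIndividualCallRate,
                alleleDepthRatioRange = alleleDepthRatioRange,
                minReproducibility = minReproducibility,
                paralogHammingThreshold = paralogHammingThreshold,
                hetRange = hetRange, mafRange = mafRange,
                hweAlpha = hweAlpha, hweCorrection = hweCorrection,
                ldR2Max = ldR2Max)
    ranges <- c("snpPositionRange", "depthRange", "alleleDepthRatioRange",
                "hetRange", "mafRange")
    for (r in ranges)
        if (length(cfg[[r]]) != 2L || cfg[[r]][1L] > cfg[[r]][2L])
            stop(r, " must be an ordered (low, high) pair")
    class(cfg) <- "filterConfig"
    cfg
}

# normalized Hamming distance between two tags over their shared prefix
.tagDistance <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    if (n == 0L) return(1)
    av <- strsplit(substr(a, 1L, n), "")[[1L]]
    bv <- strsplit(substr(b, 1L, n), "")[[1L]]
    mean(av != bv)
}

# remove later member of any tag pair closer than the threshold
.paralogFilter <- function(meta, threshold) {
    tags <- meta$tag_sequence
    n <- length(tags)
    if (n < 2L) return(rep(TRUE, n))
    keep <- rep(TRUE, n)
    for (j in 2:n) {
        for (i in which(keep[seq_len(j - 1L)])) {
            if (.tagDistance(tags[i], tags[j]) < threshold) {
                keep[j] <- FALSE
                break
            }
        }
    }
    keep
}

#' Apply the thirteen-step SNP selection cascade
#'
#' Runs the full locus-selection cascade in its fixed order:
#' (1) tags carrying exactly one SNP; (2) tag length; (3) SNP position;
#' (4) mean total read depth; (5) locus call rate; (6) individual call
#' rate (drops individuals); (7) allele read-depth balance;
#' (8) reproducibility; (9) paralog removal by tag similarity;
#' (10) observed heterozygosity; (11) minor allele frequency;
#' (12) Hardy-Weinberg equilibrium; (13) LD pruning. Counts are
#' order-dependent; the report records loci and individuals remaining
#' after every step.
#'
#' @param metadata SNP metadata data.frame (see [readSNPMetadata()])
#'   covering every locus in \code{genotypes}.
#' @param genotypes GenotypeMatrix of the discovery individuals (used by
#'   steps 6, 12 and 13).
#' @param config a [filterConfig()].
#' @return a [FilterReport-class].
#' @export
applyFilterCascade <- function(metadata, genotypes, config = filterConfig()) {
    g <- genotypeCalls(genotypes)
    loci <- colnames(g)
    if (!all(loci %in% metadata$locus_id))
        stop("genotype loci missing from metadata: ",
             paste(setdiff(loci, metadata$locus_id), collapse = ", "))
    meta <- metadata[match(loci, metadata$locus_id), , drop = FALSE]
    inds <- rownames(g)
    steps <- list(list(step = "raw", loci = length(loci),
                       individuals = length(inds)))
    note <- function(name) {
        steps[[length(steps) + 1L]] <<- list(step = name, loci = length(loci),
                                             individuals = length(inds))
    }
    keepLoci <- function(ok) {
        ok[is.na(ok)] <- FALSE
        loci <<- loci[ok]
        meta <<- meta[ok, , drop = FALSE]
    }

    # 1. single-SNP tags: clones represented more than once, or annotated
    #    with >1 SNP, are discarded wholesale
    cloneN <- pmax(as.vector(table(meta$clone_id)[meta$clone_id]),
                   meta$snp_count_in_clone)
    keepLoci(cloneN == 1)
    note("single SNP per tag")

    keepLoci(nchar(meta$tag_sequence) >= config$minTagLength)
    note("tag length")

    keepLoci(meta$snp_position >= config$snpPositionRange[1L] &
             meta$snp_position <= config$snpPositionRange[2L])
    note("SNP position")

    depth <- meta$mean_depth_ref + meta$mean_depth_alt
    keepLoci(depth >= config$depthRange[1L] & depth <= config$depthRange[2L])
    note("read depth")

    keepLoci(meta$call_rate >= config$minLocusCallRate)
    note("locus call rate")

    # 6. individual call rate on the surviving loci
    sub <- g[inds, loci, drop = FALSE]
    rate <- rowMeans(!is.na(sub))
    inds <- inds[rate >= config$minIndividualCallRate]
    note("individual call rate")

    frac <- meta$mean_depth_alt / (meta$mean_depth_ref + meta$mean_depth_alt)
    keepLoci(frac >= config$alleleDepthRatioRange[1L] &
             frac <= config$alleleDepthRatioRange[2L])
    note("allele depth ratio")

    keepLoci(meta$reproducibility > config$minReproducibility)
    note("reproducibility")

    keepLoci(.paralogFilter(meta, config$paralogHammingThreshold))
    note("paralogs")

    keepLoci(meta$het_obs >= config$hetRange[1L] &
             meta$het_obs <= config$hetRange[2L])
    note("heterozygosity")

    keepLoci(meta$maf >= config$mafRange[1L] &
             meta$maf <= config$mafRange[2L])
    note("minor allele frequency")

    # 12. exact HWE test on the surviving individuals
    if (length(loci)) {
        sub <- g[inds, loci, drop = FALSE]
        pvals <- vapply(seq_len(ncol(sub)), function(j) {
            v <- sub[, j]
            suppressWarnings(hweExactTest(sum(v == 0L, na.rm = TRUE),
                                          sum(v == 1L, na.rm = TRUE),
                                          sum(v == 2L, na.rm = TRUE)))
        }, numeric(1))
        alpha <- config$hweAlpha
        if (config$hweCorrection == "bonferroni")
            alpha <- alpha / length(pvals)
        keepLoci(is.na(pvals) | pvals >= alpha)
    }
    note("Hardy-Weinberg equilibrium")

    if (length(loci) >= 2L) {
        kept <- ldPrune(g[inds, loci, drop = FALSE], config$ldR2Max)
        keepLoci(loci %in% kept)
    }
    note("linkage equilibrium")

    steps <- do.call(rbind, lapply(steps, as.data.frame))
    new("FilterReport", steps = steps, loci = loci, individuals = inds,
        config = unclass(config))
}
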