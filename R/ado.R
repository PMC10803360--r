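#' Allelic dropout rate from replicate sample pairs
#'
#' For every original/replicate pair, allelic dropout (ADO) is estimated
#' as the fraction of heterozygous comparisons that disagree: loci called
#' in both runs where one call is heterozygous and the other homozygous,
#' divided by co-called loci with at least one heterozygous call. Pairs
#' with no heterozygous locus carry no information and are excluded from
#' the mean (flagged in the per-pair table).
#'
#' @param x GenotypeMatrix with \code{replicateOf} links.
#' @return list with \code{perPair} (data.frame: original, replicate, ADO,
#'   loci compared, het loci, pair amplification rate, informative flag),
#'   \code{mean}, \code{se} and \code{nPairs} (informative pairs).
#' @export
adoRate <- function(x) {
    ro <- replicateOf(x)
    if (!length(ro)) stop("no replicate pairs declared in the matrix")
    g <- genotypeCalls(x)
    amp <- rowMeans(!is.na(g))
    rows <- lapply(seq_along(ro), function(k) {
        rep_id <- names(ro)[k]; orig_id <- ro[[k]]
        a <- g[orig_id, ]; b <- g[rep_id, ]
        shared <- !is.na(a) & !is.na(b)
        het <- shared & (a == 1L | b == 1L)
        # het-vs-hom discordance only; hom-vs-opposite-hom (impossible
        # under pure dropout) is not counted
        discord <- het & ((a == 1L & b != 1L) | (b == 1L & a != 1L))
        data.frame(original = orig_id, replicate = rep_id,
                   ado = if (sum(het)) sum(discord) / sum(het) else NA_real_,
                   loci_compared = sum(shared), het_loci = sum(het),
                   amp_rate = mean(amp[c(orig_id, rep_id)]),
                   informative = sum(het) > 0L)
    })
    perPair <- do.call(rbind, rows)
    est <- perPair$ado[perPair$informative]
    list(perPair = perPair,
         mean = mean(est),
         se = if (length(est) > 1L) stats::sd(est) / sqrt(length(est)) else 0,
         nPairs = length(est))
}

#' Expected within-individual mismatch budget
#'
#' The back-of-envelope error budget used to pick the clustering cut
#' height: an allelic dropout rate of \code{ado} over \code{nLoci} loci
#' implies about \code{ado * nLoci} allele mismatches between two samples
#' of the same individual (e.g. 0.025 x 47 = 1.2 SNP).
#'
#' @param ado allelic dropout rate in [0, 1].
#' @param nLoci number of genotyped loci.
#' @return expected mismatch count (numeric).
#' @export
errorBudget <- function(ado, nLoci) {
    if (ado < 0 || ado > 1) stop("ado must lie in [0, 1]")
    ado * nLoci
}
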