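#' Per-locus allele frequencies
#'
#' @param x GenotypeMatrix.
#' @return data.frame per locus: \code{p} (alternative-allele frequency,
#'   missing calls excluded), \code{n} (called diploids) and \code{maf}.
#'   Loci with zero calls get NA with a warning.
#' @export
alleleFrequencies <- function(x) {
    g <- genotypeCalls(x)
    n <- colSums(!is.na(g))
    alt <- colSums(g, na.rm = TRUE)        # code == alt allele count
    p <- ifelse(n > 0, alt / (2 * n), NA_real_)
    if (any(n == 0))
        warning("loci with zero calls: ",
                paste(colnames(g)[n == 0], collapse = ", "))
    data.frame(locus_id = colnames(g), p = p, n = as.integer(n),
               maf = pmin(p, 1 - p), row.names = NULL)
}

#' Genetic diversity summaries
#'
#' Per-locus observed heterozygosity Ho, Nei's unbiased gene diversity
#' Hs = 2n/(2n-1) * 2p(1-p), allelic richness A rarefied to the smallest
#' per-locus sample of gene copies, and the inbreeding coefficient
#' F_IS = 1 - Ho/Hs (NA at monomorphic loci), plus means and standard
#' errors across loci.
#'
#' @param x GenotypeMatrix with >= 2 called individuals per locus.
#' @return list with \code{perLocus} (data.frame) and \code{summary}
#'   (mean and SE per statistic across loci; \code{FisOverall} is
#'   1 - mean(Ho)/mean(Hs)).
#' @export
diversityStats <- function(x) {
    g <- genotypeCalls(x)
    n <- colSums(!is.na(g))
    if (any(n < 2))
        stop("diversity needs >= 2 called individuals at every locus; ",
             "offending loci: ", paste(colnames(g)[n < 2], collapse = ", "))
    nAlt <- colSums(g, na.rm = TRUE)
    p <- nAlt / (2 * n)
    Ho <- colMeans(g == 1L, na.rm = TRUE)
    Hs <- (2 * n / (2 * n - 1)) * 2 * p * (1 - p)
    Fis <- ifelse(Hs > 0, 1 - Ho / Hs, NA_real_)
    gMin <- min(2 * n)
    A <- vapply(seq_along(p), function(j) {
        cnt <- c(2 * n[j] - nAlt[j], nAlt[j])
        cnt <- cnt[cnt > 0]
        sum(1 - exp(lchoose(2 * n[j] - cnt, gMin) - lchoose(2 * n[j], gMin)))
    }, numeric(1))
    perLocus <- data.frame(locus_id = colnames(g), n = as.integer(n),
                           p = p, Ho = Ho, Hs = Hs, A = A, Fis = Fis,
                           row.names = NULL)
    se <- function(v) {
        v <- v[!is.na(v)]
        if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
    }
    summary <- data.frame(
        stat = c("Ho", "Hs", "A", "Fis"),
        mean = c(mean(Ho), mean(Hs), mean(A), mean(Fis, na.rm = TRUE)),
        se = c(se(Ho), se(Hs), se(A), se(Fis)))
    list(perLocus = perLocus, summary = summary,
         FisOverall = 1 - mean(Ho) / mean(Hs))
}

# Ritland (1996) moment estimator for one pair; x/y are allele dosages
# scaled to [0,1], p the reference-population alternative-allele
# frequencies. Biallelic loci carry weight n_alleles - 1 = 1 each.
.ritlandPair <- function(g1, g2, p) {
    ok <- !is.na(g1) & !is.na(g2) & p > 0 & p < 1
    if (!any(ok)) return(NA_real_)
    xa <- g1[ok] / 2; ya <- g2[ok] / 2
    pa <- p[ok]
    mean(2 * (xa * ya / pa + (1 - xa) * (1 - ya) / (1 - pa) - 1))
}

#' Ritland pairwise relatedness for selected pairs
#'
#' The Ritland (1996) correlation estimator of pairwise relatedness,
#' weighting allele sharing by population allele frequencies; its
#' expectation is 1 for clones, 0.5 for parent-offspring or full
#' siblings, 0.25/0.125 for second/third-order kin and 0 for unrelated
#' pairs. Loci fixed in the reference frequencies (p of 0 or 1) are
#' skipped.
#'
#' @param x GenotypeMatrix.
#' @param pairs two-column matrix or data.frame of sample ids.
#' @param freqs optional numeric vector of alternative-allele frequencies
#'   in locus order (defaults to frequencies estimated from \code{x}).
#' @return numeric vector of relatedness estimates, one per pair (NA when
#'   a pair shares no usable locus).
#' @export
ritlandPairs <- function(x, pairs, freqs = NULL) {
    g <- genotypeCalls(x)
    p <- if (is.null(freqs)) alleleFrequencies(x)$p else freqs
    if (length(p) != ncol(g))
        stop("freqs must supply one frequency per locus")
    if (any(p <= 0 | p >= 1, na.rm = TRUE))
        warning("loci with fixed reference frequencies skipped")
    pairs <- as.matrix(pairs)
    vapply(seq_len(nrow(pairs)), function(k)
        .ritlandPair(g[pairs[k, 1L], ], g[pairs[k, 2L], ], p), numeric(1))
}

#' Full pairwise Ritland relatedness matrix
#'
#' @param x GenotypeMatrix (one row per individual).
#' @param freqs optional reference allele frequencies (see
#'   [ritlandPairs()]).
#' @param groups optional named vector (e.g. roost per individual); when
#'   given, mean within-group relatedness with SE is reported as well.
#' @return list with \code{matrix} (symmetric, NA diagonal) and, when
#'   \code{groups} is supplied, \code{byGroup}.
#' @export
ritlandRelatedness <- function(x, freqs = NULL, groups = NULL) {
    ids <- sampleIds(x)
    n <- length(ids)
    if (n < 2L) stop("relatedness needs at least two individuals")
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs <- cbind(ids[idx[, 1L]], ids[idx[, 2L]])
    r <- ritlandPairs(x, pairs, freqs)
    M <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    M[idx] <- r
    M[idx[, 2:1, drop = FALSE]] <- r
    out <- list(matrix = M)
    if (!is.null(groups)) {
        gg <- groups[ids]
        sameGroup <- gg[idx[, 1L]] == gg[idx[, 2L]]
        grp <- gg[idx[, 1L]]
        rows <- lapply(split(r[sameGroup], grp[sameGroup]), function(v) {
            v <- v[!is.na(v)]
            data.frame(mean_r = mean(v), se = if (length(v) > 1L)
                stats::sd(v) / sqrt(length(v)) else 0, n_pairs = length(v))
        })
        byGroup <- do.call(rbind, rows)
        out$byGroup <- cbind(data.frame(group = rownames(byGroup)), byGroup,
                             row.names = NULL)
    }
    out
}
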