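#' Genetic diversity across random locus subsets
#'
#' Evaluates how stable diversity estimates are when only a subset of the
#' candidate panel is genotyped: for each requested subset size, loci are
#' drawn without replacement \code{nPerm} times and mean observed
#' heterozygosity (Ho), unbiased gene diversity (Hs) and the inbreeding
#' coefficient F_IS = 1 - Ho/Hs are recomputed. The permutation spread
#' (SD and 2.5/97.5 percentiles) shows how many loci are needed before
#' estimates stabilise.
#'
#' @param x GenotypeMatrix.
#' @param subsetSizes integer vector of panel sizes to evaluate; each must
#'   not exceed the locus count.
#' @param nPerm permutations per size (default 500).
#' @param seed RNG seed.
#' @return data.frame with one row per (size, statistic): mean, sd and
#'   percentile bounds over permutations.
#' @export
subsetDiversity <- function(x, subsetSizes, nPerm = 500, seed = 1) {
    L <- ncol(x)
    if (any(subsetSizes > L))
        stop("subset size exceeds the ", L, " available loci")
    if (any(subsetSizes < 1L)) stop("subset sizes must be >= 1")
    perLocus <- diversityStats(x)$perLocus
    set.seed(seed)
    out <- list()
    for (s in subsetSizes) {
        stats <- vapply(seq_len(nPerm), function(i) {
            idx <- sample.int(L, s)
            ho <- mean(perLocus$Ho[idx], na.rm = TRUE)
            hs <- mean(perLocus$Hs[idx], na.rm = TRUE)
            c(Ho = ho, Hs = hs, Fis = if (hs > 0) 1 - ho / hs else NA_real_)
        }, numeric(3))
        for (st in rownames(stats)) {
            v <- stats[st, ]
            out[[length(out) + 1L]] <- data.frame(
                size = s, stat = st, mean = mean(v, na.rm = TRUE),
                sd = stats::sd(v), lower = stats::quantile(v, 0.025,
                                                           names = FALSE),
                upper = stats::quantile(v, 0.975, names = FALSE))
        }
    }
    do.call(rbind, out)
}
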