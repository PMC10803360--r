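#' Pairwise genotypic r-squared between loci
#'
#' Composite (Burrows-style) linkage disequilibrium measured as the squared
#' Pearson correlation of 0/1/2 genotype codes over samples called at both
#' loci. Monomorphic loci have no defined correlation and return NA.
#'
#' @param x GenotypeMatrix or a coded call matrix.
#' @return symmetric numeric matrix of r-squared values (diagonal 1).
#' @export
genotypeR2 <- function(x) {
    g <- if (is(x, "GenotypeMatrix")) genotypeCalls(x) else as.matrix(x)
    r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
    r * r
}

#' Prune loci in linkage disequilibrium
#'
#' Greedy scan in locus order: a locus is dropped when its genotypic
#' r-squared with any earlier retained locus exceeds \code{r2Max}.
#' Monomorphic loci (undefined r-squared) are excluded from pruning
#' decisions and reported via the \code{flagged} attribute.
#'
#' @param x GenotypeMatrix or coded call matrix with >= 2 loci.
#' @param r2Max maximum tolerated r-squared (default 0.2).
#' @return character vector of retained locus ids, with attribute
#'   \code{flagged} listing monomorphic loci.
#' @export
ldPrune <- function(x, r2Max = 0.2) {
    g <- if (is(x, "GenotypeMatrix")) genotypeCalls(x) else as.matrix(x)
    if (ncol(g) < 2L) stop("LD pruning needs at least two loci")
    r2 <- genotypeR2(g)
    loci <- colnames(g)
    mono <- apply(g, 2L, function(v) length(unique(v[!is.na(v)])) < 2L)
    keep <- logical(ncol(g))
    for (j in seq_len(ncol(g))) {
        if (mono[j]) { keep[j] <- TRUE; next }
        earlier <- which(keep & !mono)
        earlier <- earlier[earlier < j]
        keep[j] <- !length(earlier) ||
            all(r2[j, earlier] <= r2Max + 1e-12, na.rm = TRUE)
    }
    out <- loci[keep]
    attr(out, "flagged") <- loci[mono]
    out
}
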