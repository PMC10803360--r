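#' Exact Hardy-Weinberg test (Levene's conditional distribution)
#'
#' Computes the exact two-sided p-value for departure from Hardy-Weinberg
#' proportions at a biallelic locus. Conditional on the observed allele
#' counts, the heterozygote count h follows Levene's distribution
#' \deqn{P(h) = \frac{n!}{n_{AA}! \, h! \, n_{BB}!} \;
#'       \frac{n_A! \, n_B!}{(2n)!} \; 2^{h}}
#' and the p-value is the total probability of all outcomes no more
#' probable than the observed one.
#'
#' @param nHomRef,nHet,nHomAlt non-negative genotype counts.
#' @return p-value in (0, 1]; \code{NA} (with a warning) when no
#'   individuals are present.
#' @examples
#' hweExactTest(1, 0, 1)   # 1/3
#' hweExactTest(0, 2, 0)   # 1
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
    counts <- c(nHomRef, nHet, nHomAlt)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("genotype counts must be non-negative integers")
    n <- sum(counts)
    if (n == 0L) {
        warning("HWE test undefined for zero individuals")
        return(NA_real_)
    }
    nA <- 2L * nHomRef + nHet
    nB <- 2L * nHomAlt + nHet
    if (nA == 0L || nB == 0L) return(1)   # monomorphic: nothing to test
    dist <- .leveneDistribution(n, nA)
    pObs <- dist$prob[dist$het == nHet]
    sum(dist$prob[dist$prob <= pObs * (1 + 1e-9)])
}

# all attainable heterozygote counts and their Levene probabilities,
# given n diploids and nA copies of allele A
.leveneDistribution <- function(n, nA) {
    nB <- 2L * n - nA
    hMax <- min(nA, nB)
    h <- seq.int(hMax %% 2L, hMax, by = 2L)
    lp <- lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
        lgamma((nB - h) / 2 + 1) + lgamma(nA + 1) + lgamma(nB + 1) -
        lgamma(2 * n + 1) + h * log(2)
    list(het = h, prob = exp(lp))
}
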