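#' Probability-of-identity curves for panel sizing
#'
#' For each biallelic locus with alternative-allele frequency p (q = 1-p),
#' the probability that two random individuals share a genotype is
#' \deqn{P_{ID} = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2}
#' and for two full siblings
#' \deqn{P_{IDsib} = 0.25 + 0.5\sum p_i^2 + 0.5(\sum p_i^2)^2
#'       - 0.25 \sum p_i^4.}
#' Cumulative products over the supplied locus order determine how many
#' loci are needed before the probability of a chance multilocus match
#' falls below \code{threshold}.
#'
#' @param p numeric vector of per-locus allele frequencies, strictly
#'   inside (0, 1).
#' @param threshold acceptance threshold for a usable panel
#'   (default 1e-4, i.e. exclusion probability > 99.99\%).
#' @return a [PIDCurve-class].
#' @examples
#' pc <- pidCurves(rep(0.5, 10))
#' as.data.frame(pc)
#' @export
pidCurves <- function(p, threshold = 1e-4) {
    if (any(p <= 0 | p >= 1))
        stop("allele frequencies must lie strictly in (0, 1)")
    q <- 1 - p
    sum2 <- p^2 + q^2
    sum4 <- p^4 + q^4
    pid <- sum4 + (2 * p * q)^2
    pidsib <- 0.25 + 0.5 * sum2 + 0.5 * sum2^2 - 0.25 * sum4
    cumPid <- cumprod(pid)
    cumSib <- cumprod(pidsib)
    firstBelow <- function(v) {
        k <- which(v < threshold)
        if (length(k)) k[1L] else NA_integer_
    }
    new("PIDCurve", locusPID = pid, locusPIDsib = pidsib,
        cumPID = cumPid, cumPIDsib = cumSib, threshold = threshold,
        minLociUnrelated = firstBelow(cumPid), minLociSib = firstBelow(cumSib))
}
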