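#' Binomial misassignment model for a clustering
#'
#' Treats every pairwise allele comparison as a Bernoulli trial and fits
#' separate binomial distributions to within-group mismatch counts
#' (genotyping error) and between-group counts (biological variation).
#' The number of trials is 2 x the median number of co-called loci. The
#' overlap between the upper 0.995 quantile of the within distribution
#' and the lower 0.005 quantile of the between distribution measures the
#' risk of misassigning scats to individuals at the chosen cut height.
#'
#' @param mm a [MismatchMatrix-class].
#' @param assignment a [GroupAssignment-class] over the same samples.
#' @return a [MisassignmentModel-class]; \code{defined} is FALSE (with a
#'   warning) when the assignment contains no within-group pair.
#' @export
misassignmentModel <- function(mm, assignment) {
    gid <- groupMembership(assignment)
    ids <- names(gid)
    M <- mismatchCounts(mm)[ids, ids, drop = FALSE]
    L <- lociCompared(mm)[ids, ids, drop = FALSE]
    ut <- upper.tri(M)
    same <- outer(gid, gid, "==")[ut]
    within <- M[ut][same]
    between <- M[ut][!same]
    nTrials <- as.integer(round(2 * stats::median(L[ut])))
    if (!length(within) || !length(between)) {
        warning("misassignment model undefined: need at least one ",
                "within-group and one between-group pair")
        return(new("MisassignmentModel", nTrials = nTrials,
                   pWithin = NA_real_, pBetween = NA_real_,
                   upperWithinQ = NA_real_, lowerBetweenQ = NA_real_,
                   overlapWidth = NA_real_, misassignMass = NA_real_,
                   withinCounts = as.numeric(within),
                   betweenCounts = as.numeric(between), defined = FALSE))
    }
    pW <- min(1, mean(within) / nTrials)
    pB <- min(1, mean(between) / nTrials)
    upperW <- stats::qbinom(0.995, nTrials, pW)
    lowerB <- stats::qbinom(0.005, nTrials, pB)
    overlap <- max(0, upperW - lowerB)
    mass <- (1 - stats::pbinom(upperW, nTrials, pW)) +
        stats::pbinom(upperW, nTrials, pB)
    new("MisassignmentModel", nTrials = nTrials, pWithin = pW,
        pBetween = pB, upperWithinQ = as.numeric(upperW),
        lowerBetweenQ = as.numeric(lowerB), overlapWidth = overlap,
        misassignMass = mass, withinCounts = as.numeric(within),
        betweenCounts = as.numeric(between), defined = TRUE)
}
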