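#' Construct a GenotypeMatrix
#'
#' @param calls matrix of genotype codes (0 hom-ref, 1 het, 2 hom-alt, NA
#'   missing) with sample ids as rownames and locus ids as colnames.
#' @param replicateOf named character vector: names are replicate sample
#'   ids, values the original sample ids they re-genotype.
#' @param sampleMeta optional data.frame of per-sample annotation, rownames
#'   (or a \code{sample_id} column) identifying samples.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' m <- matrix(c(0, 1, 2, NA), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("L1", "L2")))
#' GenotypeMatrix(m)
#' @export
GenotypeMatrix <- function(calls, replicateOf = character(0),
                           sampleMeta = NULL) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (is.null(sampleMeta)) {
        sampleMeta <- data.frame()
    } else {
        sampleMeta <- as.data.frame(sampleMeta)
        if (!is.null(sampleMeta$sample_id) &&
            !identical(rownames(sampleMeta), sampleMeta$sample_id))
            rownames(sampleMeta) <- sampleMeta$sample_id
    }
    if (is.null(replicateOf)) replicateOf <- character(0)
    new("GenotypeMatrix", calls = calls,
        replicateOf = replicateOf, sampleMeta = sampleMeta)
}

#' @describeIn GenotypeMatrix sample identifiers (rownames).
#' @param x a GenotypeMatrix
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@calls))

#' @describeIn GenotypeMatrix locus identifiers (colnames).
#' @export
setMethod("locusIds", "GenotypeMatrix", function(x) colnames(x@calls))

#' @describeIn GenotypeMatrix the integer call matrix.
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

#' @describeIn GenotypeMatrix replicate-to-original links.
#' @export
setMethod("replicateOf", "GenotypeMatrix", function(x) x@replicateOf)

#' @describeIn GenotypeMatrix per-sample annotation.
#' @export
setMethod("sampleMeta", "GenotypeMatrix", function(x) x@sampleMeta)

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@calls))

#' Subset a GenotypeMatrix by samples and/or loci
#'
#' Replicate links whose partner is removed are silently dropped;
#' sample metadata rows follow the retained samples.
#'
#' @param x GenotypeMatrix
#' @param i sample index or ids
#' @param j locus index or ids
#' @param ... ignored
#' @param drop ignored, always FALSE
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@calls))
    if (missing(j)) j <- seq_len(ncol(x@calls))
    m <- x@calls[i, j, drop = FALSE]
    ro <- x@replicateOf
    ro <- ro[names(ro) %in% rownames(m) & ro %in% rownames(m)]
    sm <- x@sampleMeta
    if (nrow(sm) > 0L) sm <- sm[rownames(sm) %in% rownames(m), , drop = FALSE]
    new("GenotypeMatrix", calls = m, replicateOf = ro, sampleMeta = sm)
})

setMethod("show", "GenotypeMatrix", function(object) {
    m <- object@calls
    miss <- if (length(m)) round(100 * mean(is.na(m)), 1) else 0
    cat("GenotypeMatrix:", nrow(m), "samples x", ncol(m), "loci;",
        length(object@replicateOf), "replicate links;",
        paste0(miss, "%"), "missing calls\n")
})

setMethod("show", "FilterReport", function(object) {
    cat("FilterReport (", nrow(object@steps) - 1L, " steps ):\n", sep = "")
    print(object@steps, row.names = FALSE)
})

#' @describeIn FilterReport the per-step attrition table.
#' @param x a FilterReport
#' @export
setMethod("filterSteps", "FilterReport", function(x) x@steps)

#' @describeIn FilterReport locus ids surviving the cascade.
#' @export
setMethod("retainedLoci", "FilterReport", function(x) x@loci)

#' @describeIn FilterReport individual ids surviving the cascade.
#' @export
setMethod("retainedIndividuals", "FilterReport", function(x) x@individuals)

#' @describeIn PIDCurve loci needed to push cumulative PID below threshold.
#' @param x a PIDCurve
#' @export
setMethod("minLociUnrelated", "PIDCurve", function(x) x@minLociUnrelated)

#' @describeIn PIDCurve loci needed for cumulative PIDsib below threshold.
#' @export
setMethod("minLociSib", "PIDCurve", function(x) x@minLociSib)

setMethod("show", "PIDCurve", function(object) {
    cat("PIDCurve over", length(object@locusPID), "loci; threshold",
        object@threshold, "\n  cumulative PID reaches threshold at",
        object@minLociUnrelated, "loci; PIDsib at", object@minLociSib, "\n")
})

#' Tabulate a PIDCurve
#'
#' @param x PIDCurve
#' @param ... ignored
#' @return data.frame with per-locus and cumulative PID / PIDsib.
#' @export
as.data.frame.PIDCurve <- function(x, ...) {
    data.frame(locus = seq_along(x@locusPID), pid = x@locusPID,
               pid_sib = x@locusPIDsib, cum_pid = x@cumPID,
               cum_pid_sib = x@cumPIDsib)
}

#' @describeIn MismatchMatrix pairwise mismatch counts.
#' @param x a MismatchMatrix
#' @export
setMethod("mismatchCounts", "MismatchMatrix", function(x) x@mismatches)

#' @describeIn MismatchMatrix pairwise co-called locus counts.
#' @export
setMethod("lociCompared", "MismatchMatrix", function(x) x@lociCompared)

#' @export
setMethod("dim", "MismatchMatrix", function(x) dim(x@mismatches))

setMethod("show", "MismatchMatrix", function(object) {
    n <- nrow(object@mismatches)
    off <- object@mismatches[upper.tri(object@mismatches)]
    cat("MismatchMatrix:", n, "samples;",
        "pairwise mismatches range", min(off), "-", max(off), "\n")
})

#' @describeIn GroupAssignment sample-to-group map.
#' @param x a GroupAssignment
#' @export
setMethod("groupMembership", "GroupAssignment", function(x) x@groups)

#' @describeIn GroupAssignment representative sample per group.
#' @export
setMethod("representatives", "GroupAssignment", function(x) x@representatives)

#' @describeIn GroupAssignment the cut height h used.
#' @export
setMethod("cutHeight", "GroupAssignment", function(x) x@cutHeight)

#' @describeIn GroupAssignment members per group.
#' @export
setMethod("groupSizes", "GroupAssignment", function(x) x@sizes)

setMethod("show", "GroupAssignment", function(object) {
    cat("GroupAssignment at h =", object@cutHeight, ":",
        length(object@sizes), "groups from", length(object@groups),
        "samples (sizes", paste(range(object@sizes), collapse = "-"), ")\n")
})

setMethod("show", "MisassignmentModel", function(object) {
    if (!object@defined) {
        cat("MisassignmentModel: undefined (no within-group pairs)\n")
        return(invisible(NULL))
    }
    cat("MisassignmentModel: n =", object@nTrials, "allele trials\n",
        " p(within) =", signif(object@pWithin, 3),
        " p(between) =", signif(object@pBetween, 3), "\n",
        " 0.995 within quantile =", object@upperWithinQ,
        "; 0.005 between quantile =", object@lowerBetweenQ, "\n",
        " overlap width =", object@overlapWidth,
        "; misassignment mass =", signif(object@misassignMass, 3), "\n")
})

#' @describeIn TruthSet true individual genotype matrix.
#' @param x a TruthSet
#' @export
setMethod("trueGenotypes", "TruthSet", function(x) x@genotypes)

#' @describeIn TruthSet pedigreed dyads (type, id1, id2).
#' @export
setMethod("truthDyads", "TruthSet", function(x) x@dyads)

#' @describeIn TruthSet true sex per individual.
#' @export
setMethod("truthSex", "TruthSet", function(x) x@sex)

#' @describeIn TruthSet roost per individual.
#' @export
setMethod("truthRoost", "TruthSet", function(x) x@roost)

#' @describeIn TruthSet true alternative-allele frequency per locus.
#' @export
setMethod("trueAlleleFreqs", "TruthSet", function(x) x@alleleFreqs)

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet:", nrow(object@genotypes), "individuals x",
        ncol(object@genotypes), "loci;",
        sum(object@sex == "male"), "males /",
        sum(object@sex == "female"), "females;",
        nrow(object@dyads), "pedigreed dyads\n")
})
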