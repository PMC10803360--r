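#' @import methods
NULL

GENO_CODES <- c(0L, 1L, 2L)

#' GenotypeMatrix: sample-by-locus biallelic genotype calls
#'
#' The central container of the package. Calls are coded per locus as
#' 0 (homozygous reference), 1 (heterozygous), 2 (homozygous alternative)
#' and \code{NA} (missing / failed amplification). Rows are samples (scats,
#' replicates or consensus individuals), columns are SNP loci.
#'
#' @slot calls integer matrix with values in \{0, 1, 2, NA\}; rownames are
#'   unique sample ids, colnames unique locus ids.
#' @slot replicateOf named character vector linking re-genotyped samples to
#'   their originals: \code{names()} are replicate sample ids, values the
#'   original sample ids. May be empty.
#' @slot sampleMeta data.frame of per-sample annotation (e.g. roost,
#'   collection date, true individual for simulated data); rownames are
#'   sample ids. May have zero rows.
#'
#' @seealso [GenotypeMatrix()], [readGenotypeTable()], [cleanMatrix()]
#' @name GenotypeMatrix-class
#' @rdname GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
    representation(
        calls = "matrix",
        replicateOf = "character",
        sampleMeta = "data.frame"
    ),
    prototype(
        calls = matrix(integer(0), 0, 0),
        replicateOf = character(0),
        sampleMeta = data.frame()
    )
)

setValidity("GenotypeMatrix", function(object) {
    msg <- character(0)
    m <- object@calls
    if (!is.integer(m) && !(is.numeric(m) && length(m) == 0L))
        msg <- c(msg, "calls must be an integer matrix")
    bad <- !(m %in% GENO_CODES) & !is.na(m)
    if (any(bad))
        msg <- c(msg, "calls must be coded 0/1/2 or NA")
    if (nrow(m) > 0L && is.null(rownames(m)))
        msg <- c(msg, "calls must have sample ids as rownames")
    if (ncol(m) > 0L && is.null(colnames(m)))
        msg <- c(msg, "calls must have locus ids as colnames")
    if (anyDuplicated(rownames(m)))
        msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(m)))
        msg <- c(msg, "duplicate locus ids")
    ro <- object@replicateOf
    if (length(ro)) {
        if (is.null(names(ro)) || any(!nzchar(names(ro))))
            msg <- c(msg, "replicateOf must be named (replicate -> original)")
        else {
            if (!all(names(ro) %in% rownames(m)) || !all(ro %in% rownames(m)))
                msg <- c(msg, "replicateOf refers to unknown sample ids")
            if (any(names(ro) == ro))
                msg <- c(msg, "a sample cannot be a replicate of itself")
        }
    }
    sm <- object@sampleMeta
    if (nrow(sm) > 0L && !all(rownames(sm) %in% rownames(m)))
        msg <- c(msg, "sampleMeta rownames must be sample ids")
    if (length(msg)) msg else TRUE
})

#' FilterReport: attrition record of the SNP panel filter cascade
#'
#' @slot steps data.frame with columns \code{step}, \code{loci},
#'   \code{individuals}: loci and individuals remaining after each filter,
#'   first row being the raw input.
#' @slot loci character, locus ids surviving the full cascade.
#' @slot individuals character, individual ids surviving the cascade.
#' @slot config list, the [filterConfig()] used (plus any flags raised).
#' @name FilterReport-class
#' @rdname FilterReport-class
#' @exportClass FilterReport
setClass("FilterReport",
    representation(steps = "data.frame", loci = "character",
                   individuals = "character", config = "list")
)

setValidity("FilterReport", function(object) {
    st <- object@steps
    if (!all(c("step", "loci", "individuals") %in% names(st)))
        return("steps needs columns step/loci/individuals")
    if (is.unsorted(rev(st$loci)))
        return("loci-remaining sequence must be non-increasing")
    if (is.unsorted(rev(st$individuals)))
        return("individuals-remaining sequence must be non-increasing")
    TRUE
})

#' PIDCurve: probability-of-identity panel sizing
#'
#' Per-locus and cumulative probabilities that two random unrelated
#' individuals (PID) or two full siblings (PIDsib) share a multilocus
#' genotype, in the supplied locus order.
#'
#' @slot locusPID,locusPIDsib numeric per-locus probabilities in (0, 1].
#' @slot cumPID,cumPIDsib cumulative products over the locus order.
#' @slot threshold numeric, the acceptance threshold (default 1e-4).
#' @slot minLociUnrelated,minLociSib integer, smallest number of loci whose
#'   cumulative probability falls below the threshold (NA if never).
#' @name PIDCurve-class
#' @rdname PIDCurve-class
#' @exportClass PIDCurve
setClass("PIDCurve",
    representation(locusPID = "numeric", locusPIDsib = "numeric",
                   cumPID = "numeric", cumPIDsib = "numeric",
                   threshold = "numeric",
                   minLociUnrelated = "integer", minLociSib = "integer")
)

setValidity("PIDCurve", function(object) {
    msg <- character(0)
    if (any(object@locusPID <= 0 | object@locusPID > 1))
        msg <- c(msg, "per-locus PID must lie in (0,1]")
    if (any(object@locusPIDsib < object@locusPID - 1e-12))
        msg <- c(msg, "PIDsib must be >= PID at every locus")
    if (is.unsorted(rev(object@cumPID)) || is.unsorted(rev(object@cumPIDsib)))
        msg <- c(msg, "cumulative curves must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' MismatchMatrix: pairwise allelic mismatch counts between samples
#'
#' For every sample pair, the number of allele mismatches summed over loci
#' called in both samples (|code difference|, so hom-ref vs hom-alt counts
#' 2), and the number of loci compared. Pairs sharing no called locus are
#' flagged and assigned maximal dissimilarity (2 x locus count).
#'
#' @slot mismatches numeric symmetric matrix, zero diagonal.
#' @slot lociCompared integer symmetric matrix of co-called locus counts.
#' @slot noOverlap logical symmetric matrix flagging undefined pairs.
#' @name MismatchMatrix-class
#' @rdname MismatchMatrix-class
#' @exportClass MismatchMatrix
setClass("MismatchMatrix",
    representation(mismatches = "matrix", lociCompared = "matrix",
                   noOverlap = "matrix")
)

setValidity("MismatchMatrix", function(object) {
    m <- object@mismatches
    msg <- character(0)
    if (!isSymmetric(unname(m))) msg <- c(msg, "mismatches must be symmetric")
    if (any(diag(m) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(m < 0)) msg <- c(msg, "mismatch counts must be non-negative")
    ok <- !object@noOverlap
    if (any(m[ok] > 2 * object@lociCompared[ok]))
        msg <- c(msg, "mismatch count cannot exceed 2 x loci compared")
    if (length(msg)) msg else TRUE
})

#' GroupAssignment: scat-to-individual grouping at a dendrogram cut
#'
#' @slot cutHeight numeric, the mismatch cut height h.
#' @slot groups named integer vector mapping each sample id to a group id.
#' @slot sizes integer vector of group sizes, named by group id.
#' @slot representatives named character, the best-amplifying member per
#'   group (the sample to carry forward for further genotyping).
#' @name GroupAssignment-class
#' @rdname GroupAssignment-class
#' @exportClass GroupAssignment
setClass("GroupAssignment",
    representation(cutHeight = "numeric", groups = "integer",
                   sizes = "integer", representatives = "character")
)

setValidity("GroupAssignment", function(object) {
    msg <- character(0)
    if (is.null(names(object@groups)))
        msg <- c(msg, "groups must be named by sample id")
    tab <- table(object@groups)
    if (!identical(as.integer(tab[as.character(names(object@sizes))]),
                   unname(object@sizes)))
        msg <- c(msg, "sizes inconsistent with groups")
    if (length(msg)) msg else TRUE
})

#' MisassignmentModel: binomial model of within/between-group mismatches
#'
#' Fits binomial distributions to within-group (genotyping error) and
#' between-group (biological variation) allele mismatch counts and reports
#' the overlap of the upper 0.995 within quantile with the lower 0.005
#' between quantile -- the diagnostic used to justify the cut height.
#'
#' @slot nTrials integer, allele comparisons per pair (2 x median loci
#'   compared).
#' @slot pWithin,pBetween binomial success probabilities.
#' @slot upperWithinQ,lowerBetweenQ the 0.995/0.005 binomial quantiles.
#' @slot overlapWidth max(0, upperWithinQ - lowerBetweenQ).
#' @slot misassignMass P(within > upper cut) + P(between <= upper cut).
#' @slot withinCounts,betweenCounts the observed mismatch counts.
#' @slot defined logical; FALSE when no within-group pair exists.
#' @name MisassignmentModel-class
#' @rdname MisassignmentModel-class
#' @exportClass MisassignmentModel
setClass("MisassignmentModel",
    representation(nTrials = "integer", pWithin = "numeric",
                   pBetween = "numeric", upperWithinQ = "numeric",
                   lowerBetweenQ = "numeric", overlapWidth = "numeric",
                   misassignMass = "numeric", withinCounts = "numeric",
                   betweenCounts = "numeric", defined = "logical")
)

#' TruthSet: simulated individuals with known pedigree, sex and roosts
#'
#' @slot genotypes integer matrix, true individual genotypes (0/1/2).
#' @slot dyads data.frame of pedigreed pairs: \code{type} (unrelated,
#'   parent_offspring, full_sib, half_sib, clone), \code{id1}, \code{id2}.
#' @slot sex named character ("male"/"female") per individual.
#' @slot roost named character per individual.
#' @slot alleleFreqs numeric true alternative-allele frequency per locus.
#' @slot config the [simulationConfig()] that generated the set.
#' @name TruthSet-class
#' @rdname TruthSet-class
#' @exportClass TruthSet
setClass("TruthSet",
    representation(genotypes = "matrix", dyads = "data.frame",
                   sex = "character", roost = "character",
                   alleleFreqs = "numeric", config = "list")
)

setValidity("TruthSet", function(object) {
    g <- object@genotypes
    if (any(!(g %in% GENO_CODES)))
        return("truth genotypes must be complete 0/1/2")
    if (!all(names(object@sex) == rownames(g)))
        return("sex must be named by individual in matrix order")
    TRUE
})
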