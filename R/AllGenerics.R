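#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("locusIds", function(x) standardGeneric("locusIds"))

#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @export
setGeneric("replicateOf", function(x) standardGeneric("replicateOf"))

#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @export
setGeneric("mismatchCounts", function(x) standardGeneric("mismatchCounts"))

#' @export
setGeneric("lociCompared", function(x) standardGeneric("lociCompared"))

#' @export
setGeneric("groupMembership", function(x) standardGeneric("groupMembership"))

#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @export
setGeneric("cutHeight", function(x) standardGeneric("cutHeight"))

#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @export
setGeneric("filterSteps", function(x) standardGeneric("filterSteps"))

#' @export
setGeneric("retainedLoci", function(x) standardGeneric("retainedLoci"))

#' @export
setGeneric("retainedIndividuals",
           function(x) standardGeneric("retainedIndividuals"))

#' @export
setGeneric("minLociUnrelated", function(x) standardGeneric("minLociUnrelated"))

#' @export
setGeneric("minLociSib", function(x) standardGeneric("minLociSib"))

#' @export
setGeneric("trueGenotypes", function(x) standardGeneric("trueGenotypes"))

#' @export
setGeneric("truthDyads", function(x) standardGeneric("truthDyads"))

#' @export
setGeneric("truthSex", function(x) standardGeneric("truthSex"))

#' @export
setGeneric("truthRoost", function(x) standardGeneric("truthRoost"))

#' @export
setGeneric("trueAlleleFreqs", function(x) standardGeneric("trueAlleleFreqs"))
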