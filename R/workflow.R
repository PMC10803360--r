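## Two-step genotyping protocol: identify individuals on the
## identification panel (step 1), then assemble consensus genotypes,
## extend representatives with the population-genetics panels, and run
## sexing and diversity/relatedness summaries (step 2).

#' Step 1: clean, cluster and diagnose an identification-panel run
#'
#' Runs the full ScatMatch-style chain on raw scat genotypes: completely
#' failed samples are set aside, amplification-rate cleaning is applied,
#' pairwise allelic mismatches are computed and clustered by average
#' linkage, the dendrogram is cut at \code{h}, and the elbow curve,
#' misassignment model and (when replicates are present) allelic dropout
#' report are produced. Deterministic given its inputs.
#'
#' @param genotypes GenotypeMatrix of all samples genotyped on panel 1.
#' @param sampleMin,locusMin cleaning thresholds (defaults 0.9 / 0.8).
#' @param h dendrogram cut height in allelic mismatches (default 1).
#' @param hMax upper end of the elbow curve (default 10).
#' @return list of class \code{scatStep1}: \code{cleaned} (GenotypeMatrix),
#'   \code{cleanLog}, \code{failed}, \code{mismatches}, \code{tree},
#'   \code{groups}, \code{elbow}, \code{misassignment}, \code{ado} (NULL
#'   without replicate pairs), and \code{nIndividuals}.
#' @export
runStepOne <- function(genotypes, sampleMin = 0.9, locusMin = 0.8,
                       h = 1, hMax = 10) {
    cl <- cleanMatrix(genotypes, sampleMin = sampleMin, locusMin = locusMin)
    cleaned <- cl$genotypes
    if (nrow(cleaned) < 2L)
        stop("fewer than two samples survive cleaning")
    mm <- pairwiseMismatches(cleaned)
    tree <- upgmaTree(mm)
    groups <- cutGroups(tree, h, cleaned)
    elbow <- elbowCurve(tree, hMax)
    mis <- suppressWarnings(misassignmentModel(mm, groups))
    ado <- if (length(replicateOf(cleaned))) adoRate(cleaned) else NULL
    structure(list(cleaned = cleaned, cleanLog = cl$log, failed = cl$failed,
                   mismatches = mm, tree = tree, groups = groups,
                   elbow = elbow, misassignment = mis, ado = ado,
                   nIndividuals = length(groupSizes(groups)),
                   h = h, sampleMin = sampleMin, locusMin = locusMin),
              class = "scatStep1")
}

#' Majority-rule consensus genotypes per individual
#'
#' For each group, every locus takes the most frequent non-missing call
#' among the group's samples; ties and all-missing loci give a missing
#' consensus call.
#'
#' @param genotypes cleaned GenotypeMatrix.
#' @param assignment a [GroupAssignment-class] over its samples.
#' @param prefix individual id prefix (default "IND").
#' @return GenotypeMatrix with one row per individual; \code{sampleMeta}
#'   records group, size and representative sample.
#' @export
consensusGenotypes <- function(genotypes, assignment, prefix = "IND") {
    g <- genotypeCalls(genotypes)
    gid <- groupMembership(assignment)
    if (!all(names(gid) %in% rownames(g)))
        stop("assignment covers samples absent from the genotype matrix")
    groups <- sort(unique(gid))
    ids <- sprintf("%s%02d", prefix, groups)
    cons <- matrix(NA_integer_, length(groups), ncol(g),
                   dimnames = list(ids, colnames(g)))
    for (k in seq_along(groups)) {
        rows <- g[names(gid)[gid == groups[k]], , drop = FALSE]
        cons[k, ] <- apply(rows, 2L, function(v) {
            v <- v[!is.na(v)]
            if (!length(v)) return(NA_integer_)
            tab <- tabulate(v + 1L, 3L)
            top <- which(tab == max(tab))
            if (length(top) > 1L) NA_integer_ else top - 1L
        })
    }
    reps <- representatives(assignment)[as.character(groups)]
    meta <- data.frame(sample_id = ids, group = groups,
                       n_scats = as.integer(groupSizes(assignment)[
                           as.character(groups)]),
                       representative = unname(reps), row.names = ids)
    GenotypeMatrix(cons, sampleMeta = meta)
}

#' Step 2: consensus, extended panels, sexing and population genetics
#'
#' Builds majority consensus genotypes on the identification panel, adds
#' the population-genetics panels genotyped on each group's
#' representative scat after dropping panel-2/3 loci below the step-2
#' amplification minimum, then computes diversity statistics, Ritland
#' relatedness and individual sex.
#'
#' @param step1 result of [runStepOne()].
#' @param panel23 optional GenotypeMatrix of representative scats on the
#'   additional panels; representatives without panel-2/3 data keep NA
#'   there (with a warning).
#' @param rfu optional RFU table (sample_id, marker, rfu) for sexing.
#' @param locusMin2 minimum panel-2/3 locus amplification rate
#'   (default 0.5).
#' @param maxSexSamples per-individual sexing sample budget (default 3).
#' @return list of class \code{scatStep2}: \code{consensus}
#'   (GenotypeMatrix over the combined locus set), \code{lociStep1},
#'   \code{lociStep2}, \code{diversity}, \code{relatedness}, \code{sex}
#'   (NULL without RFU data) and \code{sexRatios}.
#' @export
runStepTwo <- function(step1, panel23 = NULL, rfu = NULL, locusMin2 = 0.5,
                       maxSexSamples = 3) {
    cons <- consensusGenotypes(step1$cleaned, step1$groups)
    loci1 <- locusIds(cons)
    loci2 <- character(0)
    if (!is.null(panel23)) {
        lr <- colMeans(!is.na(genotypeCalls(panel23)))
        keep <- names(lr)[lr >= locusMin2]
        loci2 <- setdiff(keep, loci1)   # union, panel-1 copy wins
        reps <- sampleMeta(cons)$representative
        ext <- matrix(NA_integer_, nrow(cons), length(loci2),
                      dimnames = list(sampleIds(cons), loci2))
        have <- reps %in% sampleIds(panel23)
        if (any(!have))
            warning("representatives without panel-2/3 data: ",
                    paste(reps[!have], collapse = ", "))
        ext[have, ] <- genotypeCalls(panel23)[reps[have], loci2,
                                              drop = FALSE]
        cons <- GenotypeMatrix(cbind(genotypeCalls(cons), ext),
                               sampleMeta = sampleMeta(cons))
    }
    keepL <- colSums(!is.na(genotypeCalls(cons))) >= 2L
    div <- diversityStats(cons[, locusIds(cons)[keepL]])
    rel <- ritlandRelatedness(cons[, locusIds(cons)[keepL]])
    sexTab <- NULL
    ratios <- NULL
    if (!is.null(rfu)) {
        sc <- callSampleSexTable(rfu)
        sexTab <- individualSexTable(sc, step1$groups, maxSexSamples)
        ratios <- c(confirmed = suppressWarnings(
                        sexRatio(sexTab$category, includeLikely = FALSE)),
                    all = suppressWarnings(
                        sexRatio(sexTab$category, includeLikely = TRUE)))
    }
    structure(list(consensus = cons, lociStep1 = loci1, lociStep2 = loci2,
                   diversity = div, relatedness = rel, sex = sexTab,
                   sexRatios = ratios),
              class = "scatStep2")
}

#' Read a project configuration file
#'
#' YAML with file paths (\code{panel1_genotypes}, optional
#' \code{panel23_genotypes}, \code{rfu}, \code{metadata},
#' \code{replicates}) and parameters (\code{sample_min}, \code{locus_min},
#' \code{h}, \code{locus_min_step2}).
#'
#' @param path YAML file.
#' @return list of class \code{projectConfig}.
#' @export
readProjectConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$panel1_genotypes))
        stop("project config must name panel1_genotypes")
    defaults <- list(sample_min = 0.9, locus_min = 0.8, h = 1,
                     locus_min_step2 = 0.5)
    for (nm in names(defaults))
        if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    for (f in c("panel1_genotypes", "panel23_genotypes", "rfu", "metadata",
                "replicates"))
        if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
            stop("configured file does not exist: ", cfg[[f]])
    class(cfg) <- "projectConfig"
    cfg
}

#' Run the two-step protocol from a project configuration
#'
#' Reads the configured inputs, runs [runStepOne()] and [runStepTwo()],
#' and (when \code{outDir} is given) writes the group table, cleaning
#' log, elbow curve, diversity and relatedness tables as CSV plus the
#' consensus genotypes as VCF, together with a provenance block.
#'
#' @param config path to a YAML file or a \code{projectConfig} list.
#' @param outDir optional output directory.
#' @return list with elements \code{step1} and \code{step2}.
#' @export
runProject <- function(config, outDir = NULL) {
    if (is.character(config)) config <- readProjectConfig(config)
    meta <- if (!is.null(config$metadata))
        readSNPMetadata(config$metadata) else NULL
    repl <- if (!is.null(config$replicates))
        utils::read.csv(config$replicates, colClasses = "character")
    else character(0)
    gm <- readGenotypeTable(config$panel1_genotypes, metadata = meta,
                            replicateOf = repl)
    step1 <- runStepOne(gm, sampleMin = config$sample_min,
                        locusMin = config$locus_min, h = config$h)
    panel23 <- if (!is.null(config$panel23_genotypes))
        readGenotypeTable(config$panel23_genotypes, metadata = meta)
    else NULL
    rfu <- if (!is.null(config$rfu)) readRFUTable(config$rfu) else NULL
    step2 <- runStepTwo(step1, panel23 = panel23, rfu = rfu,
                        locusMin2 = config$locus_min_step2)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        w <- function(x, f) utils::write.csv(
            x, file.path(outDir, f), row.names = FALSE)
        gid <- groupMembership(step1$groups)
        w(data.frame(sample_id = names(gid), group = gid), "groups.csv")
        w(step1$cleanLog, "clean_log.csv")
        w(step1$elbow, "elbow.csv")
        w(step2$diversity$perLocus, "diversity_per_locus.csv")
        w(step2$diversity$summary, "diversity_summary.csv")
        rel <- step2$relatedness$matrix
        w(data.frame(individual = rownames(rel), rel, check.names = FALSE),
          "relatedness.csv")
        if (!is.null(step2$sex)) w(step2$sex, "sex.csv")
        if (!is.null(meta))
            writeConsensusVCF(step2$consensus[,
                intersect(locusIds(step2$consensus), meta$locus_id)],
                meta, file.path(outDir, "consensus.vcf"))
        prov <- c(paste("scatID version:",
                        as.character(utils::packageVersion("scatID"))),
                  paste("run at:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                  paste("config:", paste(deparse(unclass(config)),
                                         collapse = " ")))
        writeLines(prov, file.path(outDir, "provenance.txt"))
    }
    list(step1 = step1, step2 = step2)
}
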