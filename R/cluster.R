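## ScatMatch-style core: amplification-rate cleaning, pairwise allelic
## mismatches, average-linkage clustering and the cut-height diagnostics.

#' Per-sample and per-locus amplification rates
#'
#' @param x GenotypeMatrix.
#' @return list with \code{sample} (fraction of loci called per sample),
#'   \code{locus} (fraction of samples called per locus) and
#'   \code{failed} (samples with no call at all).
#' @export
amplificationRates <- function(x) {
    g <- genotypeCalls(x)
    sr <- rowMeans(!is.na(g))
    lr <- colMeans(!is.na(g))
    list(sample = sr, locus = lr, failed = names(sr)[sr == 0])
}

#' Clean a scat genotype matrix on amplification rates
#'
#' Completely failed samples are removed first; then locus and sample
#' filters alternate -- loci below \code{locusMin} on the remaining
#' samples, samples below \code{sampleMin} on the remaining loci -- until
#' a fixed point is reached. A matrix already above both thresholds is
#' returned unchanged.
#'
#' @param x GenotypeMatrix.
#' @param sampleMin minimum per-sample amplification rate (default 0.9).
#' @param locusMin minimum per-locus amplification rate (default 0.8).
#' @return list with \code{genotypes} (the cleaned GenotypeMatrix),
#'   \code{log} (data.frame of every removal with its rate and the pass it
#'   fell in) and \code{failed} (ids of zero-amplification samples).
#' @export
cleanMatrix <- function(x, sampleMin = 0.9, locusMin = 0.8) {
    if (sampleMin < 0 || sampleMin > 1 || locusMin < 0 || locusMin > 1)
        stop("thresholds must lie in [0, 1]")
    log <- data.frame(id = character(0), type = character(0),
                      rate = numeric(0), pass = integer(0))
    note <- function(ids, type, rates, pass) {
        if (length(ids))
            log <<- rbind(log, data.frame(id = ids, type = type,
                                          rate = rates, pass = pass))
    }
    rates <- amplificationRates(x)
    failed <- rates$failed
    note(failed, "failed_sample", rep(0, length(failed)), 0L)
    cur <- x[setdiff(sampleIds(x), failed), ]
    pass <- 0L
    repeat {
        pass <- pass + 1L
        changed <- FALSE
        if (nrow(cur) > 0L) {
            lr <- colMeans(!is.na(genotypeCalls(cur)))
            dropL <- names(lr)[lr < locusMin]
            if (length(dropL)) {
                note(dropL, "locus", lr[dropL], pass)
                cur <- cur[, setdiff(locusIds(cur), dropL)]
                changed <- TRUE
            }
        }
        if (ncol(cur) > 0L && nrow(cur) > 0L) {
            sr <- rowMeans(!is.na(genotypeCalls(cur)))
            dropS <- names(sr)[sr < sampleMin]
            if (length(dropS)) {
                note(dropS, "sample", sr[dropS], pass)
                cur <- cur[setdiff(sampleIds(cur), dropS), ]
                changed <- TRUE
            }
        }
        if (!changed || nrow(cur) == 0L || ncol(cur) == 0L) break
    }
    if (nrow(cur) == 0L || ncol(cur) == 0L)
        warning("cleaning removed every sample or locus")
    list(genotypes = cur, log = log, failed = failed)
}

#' Pairwise allelic mismatches between samples
#'
#' For every sample pair the per-locus allele difference |code1 - code2|
#' (het vs hom = 1, opposite homozygotes = 2) is summed over loci called
#' in both samples. Pairs with no co-called locus are flagged and set to
#' the maximal dissimilarity 2 x locus count so they never cluster.
#'
#' @param x GenotypeMatrix (typically cleaned).
#' @return a [MismatchMatrix-class].
#' @export
pairwiseMismatches <- function(x) {
    g <- genotypeCalls(x)
    n <- nrow(g)
    if (n < 2L) stop("need at least two samples")
    ind <- function(code) {
        m <- (g == code)
        m[is.na(m)] <- FALSE
        storage.mode(m) <- "numeric"
        m
    }
    A0 <- ind(0L); A1 <- ind(1L); A2 <- ind(2L)
    called <- A0 + A1 + A2
    shared <- called %*% t(called)
    mism <- (A0 %*% t(A1) + A1 %*% t(A0)) +   # one allele apart
            (A1 %*% t(A2) + A2 %*% t(A1)) +
        2 * (A0 %*% t(A2) + A2 %*% t(A0))     # opposite homozygotes
    noOv <- shared == 0
    diag(noOv) <- FALSE
    mism[noOv] <- 2 * ncol(g)
    diag(mism) <- 0
    dimnames(mism) <- dimnames(shared) <- dimnames(noOv) <-
        list(rownames(g), rownames(g))
    storage.mode(shared) <- "integer"
    new("MismatchMatrix", mismatches = mism, lociCompared = shared,
        noOverlap = noOv)
}

#' Average-linkage (UPGMA) clustering of mismatch counts
#'
#' Agglomerates samples on raw allelic mismatch counts: at each step the
#' pair of clusters with the smallest mean pairwise dissimilarity merges,
#' the merge height being that mean. Ties are broken deterministically in
#' favour of the cluster pair containing the lowest original leaf index.
#'
#' @param mm a [MismatchMatrix-class] (or symmetric dissimilarity matrix).
#' @return an object of class \code{hclust} (merge, height, order,
#'   labels), usable with [cutGroups()], [elbowCurve()] and standard
#'   dendrogram plotting.
#' @export
upgmaTree <- function(mm) {
    D <- if (is(mm, "MismatchMatrix")) mismatchCounts(mm) else as.matrix(mm)
    n <- nrow(D)
    if (n < 2L) stop("need at least two samples to cluster")
    labels <- rownames(D)
    W <- D * 1.0
    diag(W) <- Inf
    active <- rep(TRUE, n)
    size <- rep(1L, n)
    minLeaf <- seq_len(n)
    clusterId <- -seq_len(n)
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        m <- min(W[active, active])
        cand <- which(W <= m + 1e-9, arr.ind = TRUE)
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
        a <- pmin(minLeaf[cand[, 1L]], minLeaf[cand[, 2L]])
        b <- pmax(minLeaf[cand[, 1L]], minLeaf[cand[, 2L]])
        pick <- order(a, b)[1L]
        i <- cand[pick, 1L]; j <- cand[pick, 2L]
        if (minLeaf[j] < minLeaf[i]) { tmp <- i; i <- j; j <- tmp }
        merge[step, ] <- c(clusterId[i], clusterId[j])
        height[step] <- W[i, j]
        upd <- active & seq_len(n) != i & seq_len(n) != j
        W[i, upd] <- (size[i] * W[i, upd] + size[j] * W[j, upd]) /
            (size[i] + size[j])
        W[upd, i] <- W[i, upd]
        active[j] <- FALSE
        W[j, ] <- Inf; W[, j] <- Inf
        size[i] <- size[i] + size[j]
        minLeaf[i] <- min(minLeaf[i], minLeaf[j])
        clusterId[i] <- step
    }
    leafOrder <- function(k) {
        if (k < 0L) return(-k)
        c(leafOrder(merge[k, 1L]), leafOrder(merge[k, 2L]))
    }
    structure(list(merge = merge, height = height,
                   order = leafOrder(n - 1L), labels = labels,
                   method = "average", call = match.call(),
                   dist.method = "allelic mismatches"),
              class = "hclust")
}

# members of each merge node, exploiting that average linkage on this
# dissimilarity yields non-decreasing heights (merges <= h are a prefix)
.mergeMembers <- function(tree) {
    n <- length(tree$height) + 1L
    mem <- vector("list", n - 1L)
    getm <- function(k) if (k < 0L) -k else mem[[k]]
    for (s in seq_len(n - 1L))
        mem[[s]] <- c(getm(tree$merge[s, 1L]), getm(tree$merge[s, 2L]))
    mem
}

#' Cut the dendrogram into putative individuals
#'
#' Groups are the clusters formed by every merge with height <= h, i.e.
#' scats within h allelic mismatches (on average) are treated as the same
#' individual. The representative of each group is its member with the
#' highest sample amplification rate (ties resolved to the
#' lexicographically first id).
#'
#' @param tree hclust object from [upgmaTree()].
#' @param h cut height in allelic mismatches (h >= 0).
#' @param genotypes optional GenotypeMatrix used to score amplification
#'   rates for representative selection; without it representatives are
#'   the lexicographically first member.
#' @return a [GroupAssignment-class].
#' @export
cutGroups <- function(tree, h, genotypes = NULL) {
    if (h < 0) stop("cut height must be non-negative")
    n <- length(tree$height) + 1L
    comp <- seq_len(n)
    mem <- .mergeMembers(tree)
    for (s in which(tree$height <= h + 1e-9))
        comp[mem[[s]]] <- n + s
    ids <- tree$labels
    # group numbering follows first appearance in dendrogram leaf order
    ordComp <- comp[tree$order]
    gid <- match(comp, unique(ordComp))
    names(gid) <- ids
    sizes <- table(gid)
    sizes <- stats::setNames(as.integer(sizes), names(sizes))
    amp <- if (!is.null(genotypes)) {
        amplificationRates(genotypes)$sample[ids]
    } else stats::setNames(rep(0, n), ids)
    reps <- vapply(names(sizes), function(gg) {
        members <- sort(ids[gid == as.integer(gg)])
        members[order(-amp[members], members)][1L]
    }, character(1))
    new("GroupAssignment", cutHeight = as.numeric(h), groups = gid,
        sizes = sizes, representatives = reps)
}

#' Elbow curve: group count against cut height
#'
#' Because merge heights are non-decreasing, the number of groups at cut
#' height h is the leaf count minus the merges at or below h; the curve is
#' monotone non-increasing and its plateau locates the mismatch threshold
#' separating genotyping error from biological variation.
#'
#' @param tree hclust object from [upgmaTree()].
#' @param hMax largest (integer) cut height to tabulate.
#' @return data.frame with columns \code{h} and \code{n_groups}.
#' @export
elbowCurve <- function(tree, hMax) {
    if (hMax < 0) stop("hMax must be non-negative")
    n <- length(tree$height) + 1L
    h <- 0:floor(hMax)
    data.frame(h = h, n_groups = vapply(
        h, function(v) n - sum(tree$height <= v + 1e-9), integer(1)))
}

#' Reorder a mismatch matrix to dendrogram leaf order
#'
#' @param mm a [MismatchMatrix-class].
#' @param tree the matching hclust object.
#' @return list with \code{matrix} (rows/columns permuted to leaf order)
#'   and \code{table} (tidy long form: row, col, mismatches) for plotting.
#' @export
heatmapOrder <- function(mm, tree) {
    M <- mismatchCounts(mm)
    if (!setequal(rownames(M), tree$labels))
        stop("mismatch matrix and dendrogram cover different samples")
    ord <- tree$labels[tree$order]
    M <- M[ord, ord]
    tab <- data.frame(row = rep(ord, times = length(ord)),
                      col = rep(ord, each = length(ord)),
                      mismatches = as.vector(M))
    list(matrix = M, table = tab)
}

#' Plot the elbow curve
#'
#' @param tree hclust object.
#' @param hMax maximum cut height shown.
#' @param ... passed to [graphics::plot()].
#' @export
plotElbow <- function(tree, hMax, ...) {
    ec <- elbowCurve(tree, hMax)
    graphics::plot(ec$h, ec$n_groups, type = "b", pch = 19,
                   xlab = "allelic mismatches allowed (h)",
                   ylab = "number of groups", ...)
}

#' Plot the ordered pairwise mismatch heat map
#'
#' @param mm a [MismatchMatrix-class].
#' @param tree the matching hclust object.
#' @param ... passed to [graphics::image()].
#' @export
plotMismatchHeatmap <- function(mm, tree, ...) {
    M <- heatmapOrder(mm, tree)$matrix
    n <- nrow(M)
    graphics::image(seq_len(n), seq_len(n), t(M[n:1, ]),
                    col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE),
                    xlab = "", ylab = "", axes = FALSE, ...)
}
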