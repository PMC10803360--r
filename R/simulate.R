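## Truth-known simulator of a scat SNP-genotyping study: HWE founders and
## pedigreed dyads at panel-like allele frequencies, per-scat
## amplification quality, allelic dropout, optional false alleles,
## replicate pairs and qPCR sexing signals.

#' Configuration of the scat-study simulator
#'
#' Defaults emulate a single-session cave survey genotyped on a ~47-SNP
#' identification panel: loci with minor allele frequency uniform on
#' [0.3, 0.5] (the panel design window), Hardy-Weinberg founders, roughly
#' ten scats per individual across seven roosts, per-scat amplification
#' quality Beta-distributed around a 0.90 mean with a long lower tail,
#' an allelic dropout rate of 0.025 (the raw replicate-pair estimate of a
#' well-performing array before quality filtering), no false alleles, and
#' ~10\% of scats re-genotyped as replicates.
#'
#' @param seed RNG seed (mandatory; the simulation is fully reproducible
#'   from the config).
#' @param nLoci number of biallelic loci (default 47).
#' @param mafRange minor-allele-frequency window, default c(0.3, 0.5).
#' @param nIndividuals unpedigreed (founder) individuals, default 20.
#' @param dyads named counts of pedigreed dyads to add:
#'   unrelated, parent_offspring, full_sib, half_sib, clone.
#' @param scatsPerIndividual either a single rate (scat counts drawn from
#'   a zero-truncated Poisson) or an explicit integer vector, one count
#'   per individual (dyad members included, in order).
#' @param missingProb fixed per-scat locus-missing probability; when NULL
#'   (default) each scat draws its own from Beta(\code{missingBeta}).
#' @param missingBeta shape parameters of the per-scat quality
#'   distribution, default c(2, 18) (mean 0.10 missing).
#' @param adoRate allelic dropout rate on the replicate-discordance scale
#'   reported by [adoRate()] (default 0.025); internally converted to a
#'   per-call heterozygote-to-homozygote probability eps/(2 - eps).
#' @param adoQualityExponent strength of the link between scat quality
#'   and dropout: a scat whose realized missing fraction is f drops out
#'   at rate proportional to f^gamma, normalized so the pooled replicate
#'   estimate still recovers \code{adoRate} (default 3, reproducing the
#'   negative ADO-amplification relationship and the collapse of the
#'   dropout rate once low-amplification scats are cleaned away; 0
#'   decouples dropout from quality). Ignored when \code{missingProb}
#'   is fixed.
#' @param falseAlleleRate probability a homozygous call gains a spurious
#'   second allele (default 0).
#' @param replicateFraction fraction of scats re-genotyped (default 0.1).
#' @param propMale probability an individual is male (default 0.5).
#' @param nRoosts number of roosts scats are spread over (default 7).
#' @param rfu list of sexing-signal parameters: signalMean/signalSd for a
#'   present chromosome (300/50), noiseMean/noiseSd for absent-Y
#'   background (5/5), failMean/failSd for failed amplifications (20/10).
#' @return list with class \code{simulationConfig}.
#' @export
simulationConfig <- function(seed,
                             nLoci = 47,
                             mafRange = c(0.3, 0.5),
                             nIndividuals = 20,
                             dyads = c(unrelated = 0, parent_offspring = 0,
                                       full_sib = 0, half_sib = 0,
                                       clone = 0),
                             scatsPerIndividual = 10,
                             missingProb = NULL,
                             missingBeta = c(2, 18),
                             adoRate = 0.025,
                             adoQualityExponent = 3,
                             falseAlleleRate = 0,
                             replicateFraction = 0.1,
                             propMale = 0.5,
                             nRoosts = 7,
                             rfu = list(signalMean = 300, signalSd = 50,
                                        noiseMean = 5, noiseSd = 5,
                                        failMean = 20, failSd = 10)) {
    if (missing(seed)) stop("a seed is mandatory for reproducibility")
    full <- c(unrelated = 0, parent_offspring = 0, full_sib = 0,
              half_sib = 0, clone = 0)
    bad <- setdiff(names(dyads), names(full))
    if (length(bad)) stop("unknown dyad type(s): ", paste(bad, collapse = ", "))
    full[names(dyads)] <- dyads
    rates <- c(adoRate = adoRate, falseAlleleRate = falseAlleleRate,
               replicateFraction = replicateFraction, propMale = propMale)
    if (any(rates < 0 | rates > 1))
        stop("rates must lie in [0, 1]")
    if (mafRange[1L] <= 0 || mafRange[2L] > 0.5 || mafRange[1L] > mafRange[2L])
        stop("mafRange must be an ordered pair inside (0, 0.5]")
    cfg <- list(seed = as.integer(seed), nLoci = nLoci, mafRange = mafRange,
                nIndividuals = nIndividuals, dyads = full,
                scatsPerIndividual = scatsPerIndividual,
                missingProb = missingProb, missingBeta = missingBeta,
                adoRate = adoRate, adoQualityExponent = adoQualityExponent,
                falseAlleleRate = falseAlleleRate,
                replicateFraction = replicateFraction, propMale = propMale,
                nRoosts = nRoosts, rfu = rfu)
    class(cfg) <- "simulationConfig"
    cfg
}

# one Mendelian gamete (allele count contributed) per locus
.transmit <- function(g) {
    out <- g / 2
    het <- g == 1L
    out[het] <- stats::rbinom(sum(het), 1L, 0.5)
    as.integer(out)
}

.drawHWE <- function(k, p) {
    L <- length(p)
    m <- matrix(stats::rbinom(L * k, 2L, p), nrow = L, ncol = k)
    t(m)
}

#' Simulate the true individuals of a scat study
#'
#' Draws per-locus alternative-allele frequencies uniformly inside the
#' configured MAF window, founder genotypes in Hardy-Weinberg
#' proportions, and pedigreed dyads by Mendelian transmission (parents of
#' non-founder dyad members are hidden). Sexes and roosts are assigned
#' per individual. Identical configs give identical truth sets.
#'
#' @param config a [simulationConfig()].
#' @return a [TruthSet-class].
#' @export
simulateTruth <- function(config) {
    stopifnot(inherits(config, "simulationConfig"))
    set.seed(config$seed)
    L <- config$nLoci
    p <- stats::runif(L, config$mafRange[1L], config$mafRange[2L])
    geno <- list()
    dyads <- list()
    addInd <- function(g) {
        geno[[length(geno) + 1L]] <<- g
        length(geno)
    }
    for (k in seq_len(config$nIndividuals)) addInd(.drawHWE(1L, p)[1L, ])
    dy <- config$dyads
    addDyad <- function(type, g1, g2) {
        i1 <- addInd(g1); i2 <- addInd(g2)
        dyads[[length(dyads) + 1L]] <<- data.frame(type = type, i1 = i1,
                                                   i2 = i2)
    }
    for (k in seq_len(dy[["unrelated"]])) {
        f <- .drawHWE(2L, p)
        addDyad("unrelated", f[1L, ], f[2L, ])
    }
    for (k in seq_len(dy[["parent_offspring"]])) {
        par1 <- .drawHWE(1L, p)[1L, ]
        par2 <- .drawHWE(1L, p)[1L, ]
        child <- .transmit(par1) + .transmit(par2)
        addDyad("parent_offspring", par1, child)
    }
    for (k in seq_len(dy[["full_sib"]])) {
        par1 <- .drawHWE(1L, p)[1L, ]
        par2 <- .drawHWE(1L, p)[1L, ]
        addDyad("full_sib",
                .transmit(par1) + .transmit(par2),
                .transmit(par1) + .transmit(par2))
    }
    for (k in seq_len(dy[["half_sib"]])) {
        shared <- .drawHWE(1L, p)[1L, ]
        o1 <- .drawHWE(1L, p)[1L, ]
        o2 <- .drawHWE(1L, p)[1L, ]
        addDyad("half_sib",
                .transmit(shared) + .transmit(o1),
                .transmit(shared) + .transmit(o2))
    }
    for (k in seq_len(dy[["clone"]])) {
        g <- .drawHWE(1L, p)[1L, ]
        addDyad("clone", g, g)
    }
    G <- do.call(rbind, geno)
    storage.mode(G) <- "integer"
    ids <- sprintf("I%03d", seq_len(nrow(G)))
    dimnames(G) <- list(ids, sprintf("L%03d", seq_len(L)))
    dyadDf <- if (length(dyads)) {
        d <- do.call(rbind, dyads)
        data.frame(type = d$type, id1 = ids[d$i1], id2 = ids[d$i2])
    } else data.frame(type = character(0), id1 = character(0),
                      id2 = character(0))
    sex <- ifelse(stats::rbinom(nrow(G), 1L, config$propMale) == 1L,
                  "male", "female")
    roost <- sample(sprintf("R%d", seq_len(config$nRoosts)), nrow(G),
                    replace = TRUE)
    new("TruthSet", genotypes = G, dyads = dyadDf,
        sex = stats::setNames(sex, ids), roost = stats::setNames(roost, ids),
        alleleFreqs = stats::setNames(p, colnames(G)), config = unclass(config))
}

# genotyping noise for one scat: per-locus missingness first, then
# allelic dropout at heterozygous truth loci with a per-call rate tied to
# the scat's realized missing fraction (poor amplification and dropout
# share a cause: degraded DNA), then optional false alleles at
# homozygous loci. Returns the degraded call vector.
.noisyCopy <- function(g, missingProb, adoRate, gamma, momentNorm,
                       falseAlleleRate) {
    miss <- stats::runif(length(g)) < missingProb
    eps <- if (is.null(momentNorm)) adoRate
           else min(0.5, adoRate * mean(miss)^gamma / momentNorm)
    dropoutPerCall <- eps / (2 - eps)
    out <- g
    het <- which(g == 1L & !miss)
    drop <- het[stats::runif(length(het)) < dropoutPerCall]
    out[drop] <- 2L * stats::rbinom(length(drop), 1L, 0.5)
    if (falseAlleleRate > 0) {
        hom <- which(g != 1L & !miss)
        gain <- hom[stats::runif(length(hom)) < falseAlleleRate]
        out[gain] <- 1L
    }
    out[miss] <- NA_integer_
    out
}

#' Simulate scat genotypes and sexing signals from a truth set
#'
#' Each scat copies its individual's genotype and is then degraded:
#' heterozygous calls drop to a random homozygote with per-call
#' probability eps/(2 - eps) (so that the replicate-discordance estimate
#' of [adoRate()] recovers the configured eps), homozygous calls gain a
#' false allele at the configured rate, and every locus goes missing with
#' the scat's own quality-dependent probability. A fraction of scats is
#' re-genotyped as replicate pairs sharing the same DNA quality.
#' Endpoint qPCR signals for DDX3Y, SRY and Zfx are drawn per scat with
#' marker-level amplification failure tied to scat quality.
#'
#' @param truth a [TruthSet-class] from [simulateTruth()].
#' @param config the same [simulationConfig()].
#' @return list with \code{genotypes} (GenotypeMatrix whose
#'   \code{sampleMeta} carries the true individual, roost and missing
#'   probability per scat, and \code{replicateOf} the replicate links)
#'   and \code{rfu} (data.frame sample_id, marker, rfu).
#' @export
simulateScats <- function(truth, config) {
    stopifnot(is(truth, "TruthSet"), inherits(config, "simulationConfig"))
    set.seed(config$seed + 1L)
    G <- trueGenotypes(truth)
    K <- nrow(G)
    nv <- config$scatsPerIndividual
    counts <- if (length(nv) == 1L) {
        n <- stats::rpois(K, nv)
        while (any(n == 0L)) n[n == 0L] <- stats::rpois(sum(n == 0L), nv)
        n
    } else {
        if (length(nv) != K)
            stop("scatsPerIndividual must be scalar or one count per ",
                 "individual (", K, ")")
        as.integer(nv)
    }
    owner <- rep(rownames(G), counts)
    nScat <- length(owner)
    scatIds <- sprintf("S%04d", seq_len(nScat))
    mProb <- if (!is.null(config$missingProb)) {
        rep(config$missingProb, nScat)
    } else stats::rbeta(nScat, config$missingBeta[1L], config$missingBeta[2L])
    # quality-linked dropout: a scat whose realized missing fraction is f
    # drops out at rate adoRate * f^gamma / E[m^gamma], so the pooled
    # replicate-pair estimate recovers adoRate while cleaning preferentially
    # removes the error-prone scats. With a fixed missingProb the link is
    # switched off (controlled-conditions mode) and every scat uses adoRate.
    gam <- if (is.null(config$adoQualityExponent)) 0
           else config$adoQualityExponent
    momentNorm <- if (is.null(config$missingProb) && gam > 0) {
        # exact E[f^gamma] of the realized missing fraction f = X/L,
        # X | m ~ Binom(L, m), m ~ Beta(a, b) (beta-binomial quadrature)
        a <- config$missingBeta[1L]; b <- config$missingBeta[2L]
        L <- ncol(G)
        x <- 0:L
        pmf <- exp(lchoose(L, x) + lbeta(x + a, L - x + b) - lbeta(a, b))
        sum((x / L)^gam * pmf)
    } else NULL
    calls <- matrix(NA_integer_, nScat, ncol(G),
                    dimnames = list(scatIds, colnames(G)))
    for (i in seq_len(nScat))
        calls[i, ] <- .noisyCopy(G[owner[i], ], mProb[i], config$adoRate,
                                 gam, momentNorm, config$falseAlleleRate)
    nRep <- round(config$replicateFraction * nScat)
    replicateOf <- character(0)
    if (nRep > 0L) {
        repOf <- sample(scatIds, nRep)
        repIds <- paste0(repOf, "R")
        repCalls <- matrix(NA_integer_, nRep, ncol(G),
                           dimnames = list(repIds, colnames(G)))
        for (k in seq_len(nRep)) {
            i <- match(repOf[k], scatIds)
            repCalls[k, ] <- .noisyCopy(G[owner[i], ], mProb[i],
                                        config$adoRate, gam, momentNorm,
                                        config$falseAlleleRate)
        }
        calls <- rbind(calls, repCalls)
        owner <- c(owner, owner[match(repOf, scatIds)])
        mProb <- c(mProb, mProb[match(repOf, scatIds)])
        replicateOf <- stats::setNames(repOf, repIds)
    }
    meta <- data.frame(sample_id = rownames(calls),
                       individual_id = owner,
                       roost = truthRoost(truth)[owner],
                       missing_prob = mProb,
                       row.names = rownames(calls))
    gm <- GenotypeMatrix(calls, replicateOf = replicateOf, sampleMeta = meta)

    rp <- config$rfu
    sexOf <- truthSex(truth)[owner[seq_len(nScat)]]
    markers <- c("DDX3Y", "SRY", "Zfx")
    rfu <- expand.grid(sample_id = scatIds, marker = markers,
                       stringsAsFactors = FALSE)
    rfu <- rfu[order(rfu$sample_id), ]
    sex <- sexOf[match(rfu$sample_id, scatIds)]
    fail <- stats::runif(nrow(rfu)) < mProb[match(rfu$sample_id, scatIds)]
    present <- rfu$marker == "Zfx" | sex == "male"
    mu <- ifelse(present, rp$signalMean, rp$noiseMean)
    sdv <- ifelse(present, rp$signalSd, rp$noiseSd)
    mu[fail] <- rp$failMean
    sdv[fail] <- rp$failSd
    rfu$rfu <- abs(stats::rnorm(nrow(rfu), mu, sdv))
    rownames(rfu) <- NULL
    list(genotypes = gm, rfu = rfu)
}
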