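## Delimited-table and VCF input/output.
## Genotype tables are wide (first column sample id, one column per locus);
## cells carry either two-character allele strings ("CT", order-insensitive),
## 0/1/2 codes, or blanks for missing.

.sniffDelim <- function(path) {
    first <- readLines(path, n = 1L)
    if (lengths(regmatches(first, gregexpr("\t", first))) > 0L) "\t" else ","
}

.readDelim <- function(path, ...) {
    utils::read.table(path, sep = .sniffDelim(path), header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character", ...)
}

#' Read a wide genotype call table
#'
#' Parses a CSV/TSV whose first column holds sample ids and remaining
#' columns one SNP locus each. Cells may be two-character allele strings
#' (e.g. \code{"CT"}; allele order is irrelevant), integer codes 0/1/2, or
#' blank/NA for missing. Allele strings are decoded against the per-locus
#' reference and alternative alleles supplied in \code{metadata}.
#'
#' @param path file path (delimiter auto-detected between comma and tab).
#' @param metadata data.frame with columns \code{locus_id},
#'   \code{ref_allele}, \code{alt_allele} (e.g. from [readSNPMetadata()]).
#'   May be omitted when every cell is already 0/1/2 coded.
#' @param replicateOf optional named character of replicate links, or a
#'   2-column data.frame (replicate id, original id).
#' @param sampleMeta optional per-sample annotation data.frame.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypeTable <- function(path, metadata = NULL, replicateOf = character(0),
                              sampleMeta = NULL) {
    tab <- .readDelim(path)
    if (ncol(tab) < 2L)
        stop("genotype table needs a sample id column plus at least one locus")
    ids <- tab[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate sample id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    loci <- names(tab)[-1L]
    if (is.data.frame(replicateOf) && nrow(replicateOf)) {
        replicateOf <- stats::setNames(as.character(replicateOf[[2L]]),
                                       as.character(replicateOf[[1L]]))
    } else if (is.data.frame(replicateOf)) replicateOf <- character(0)
    refalt <- NULL
    if (!is.null(metadata)) {
        refalt <- metadata[match(loci, metadata$locus_id),
                           c("ref_allele", "alt_allele")]
    }
    calls <- matrix(NA_integer_, length(ids), length(loci),
                    dimnames = list(ids, loci))
    for (j in seq_along(loci)) {
        cells <- toupper(trimws(tab[[j + 1L]]))
        miss <- is.na(cells) | cells == "" | cells == "NA"
        coded <- grepl("^[0-2]$", cells)
        out <- rep(NA_integer_, length(cells))
        out[coded] <- as.integer(cells[coded])
        alle <- !miss & !coded
        if (any(alle)) {
            if (is.null(refalt) || is.na(refalt$ref_allele[j]))
                stop("allele strings at locus ", loci[j],
                     " but no ref/alt metadata supplied")
            ref <- toupper(refalt$ref_allele[j])
            alt <- toupper(refalt$alt_allele[j])
            a1 <- substr(cells[alle], 1L, 1L)
            a2 <- substr(cells[alle], 2L, 2L)
            badlen <- nchar(cells[alle]) != 2L
            badchr <- !(a1 %in% c(ref, alt)) | !(a2 %in% c(ref, alt))
            if (any(badlen | badchr)) {
                k <- which(alle)[which(badlen | badchr)[1L]]
                stop("unparseable genotype '", cells[k], "' for sample ",
                     ids[k], " at locus ", loci[j],
                     " (expected alleles ", ref, "/", alt, ")")
            }
            out[alle] <- (a1 == alt) + (a2 == alt)
        }
        calls[, j] <- out
    }
    GenotypeMatrix(calls, replicateOf = replicateOf, sampleMeta = sampleMeta)
}

#' Write a GenotypeMatrix as a wide CSV of 0/1/2 codes
#'
#' @param x GenotypeMatrix
#' @param path output file
#' @export
writeGenotypeTable <- function(x, path) {
    df <- data.frame(sample_id = sampleIds(x), genotypeCalls(x),
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    invisible(path)
}

SNP_META_COLS <- c("locus_id", "clone_id", "snp_count_in_clone",
                   "tag_sequence", "snp_position", "ref_allele", "alt_allele",
                   "mean_depth_ref", "mean_depth_alt", "call_rate",
                   "reproducibility", "het_obs", "maf")

#' Read a DArT-style SNP locus metadata table
#'
#' One row per candidate SNP with the per-locus quantities the panel filter
#' cascade consumes: tag sequence, SNP position within the tag, mean read
#' depths, call rate, reproducibility across technical replicates, observed
#' heterozygosity and minor allele frequency.
#'
#' @param path CSV/TSV with a header naming the fields
#'   (\code{locus_id, clone_id, snp_count_in_clone, tag_sequence,
#'   snp_position, ref_allele, alt_allele, mean_depth_ref, mean_depth_alt,
#'   call_rate, reproducibility, het_obs, maf}).
#' @return data.frame, numeric fields parsed; rows with missing numeric
#'   values are kept and flagged via the \code{incomplete} column.
#' @export
readSNPMetadata <- function(path) {
    if (file.size(path) == 0L || length(readLines(path, n = 2L)) < 2L) {
        warning("empty SNP metadata file: ", path)
        out <- as.data.frame(stats::setNames(
            rep(list(character(0)), length(SNP_META_COLS)), SNP_META_COLS))
        out$incomplete <- logical(0)
        return(out)
    }
    tab <- .readDelim(path)
    missing <- setdiff(SNP_META_COLS, names(tab))
    if (length(missing))
        stop("SNP metadata lacks columns: ", paste(missing, collapse = ", "))
    num <- c("snp_count_in_clone", "snp_position", "mean_depth_ref",
             "mean_depth_alt", "call_rate", "reproducibility", "het_obs",
             "maf")
    for (cc in num) tab[[cc]] <- suppressWarnings(as.numeric(tab[[cc]]))
    tab$incomplete <- apply(is.na(tab[num]), 1L, any)
    bad <- which(!is.na(tab$snp_position) &
                 tab$snp_position > nchar(tab$tag_sequence))
    if (length(bad))
        stop("snp_position beyond tag length for locus ",
             paste(tab$locus_id[bad], collapse = ", "))
    if (any(tab$mean_depth_ref < 0 | tab$mean_depth_alt < 0, na.rm = TRUE))
        stop("negative read depth in SNP metadata")
    if (any(tab$maf > 0.5 + 1e-9, na.rm = TRUE))
        stop("maf must be a minor allele frequency (<= 0.5)")
    if (any(tab$ref_allele == tab$alt_allele))
        stop("ref and alt allele identical for locus ",
             paste(tab$locus_id[tab$ref_allele == tab$alt_allele],
                   collapse = ", "))
    tab
}

#' Read a qPCR RFU table for the sexing assay
#'
#' @param path CSV/TSV with columns \code{sample_id}, \code{marker},
#'   \code{rfu}. Markers must come from DDX3Y, SRY, Zfy, Zfx.
#' @return data.frame of relative-fluorescence records, rfu numeric >= 0.
#' @export
readRFUTable <- function(path) {
    tab <- .readDelim(path)
    need <- c("sample_id", "marker", "rfu")
    if (!all(need %in% names(tab)))
        stop("RFU table needs columns ", paste(need, collapse = ", "))
    tab$rfu <- as.numeric(tab$rfu)
    if (any(is.na(tab$rfu)) || any(tab$rfu < 0))
        stop("rfu values must be non-negative numbers")
    bad <- setdiff(unique(tab$marker), SEX_MARKERS)
    if (length(bad))
        stop("unknown sex marker(s): ", paste(bad, collapse = ", "))
    tab[need]
}

#' Export consensus genotypes as VCF 4.2
#'
#' Writes one VCF record per locus with REF/ALT taken from the SNP
#' metadata and per-individual GT fields 0/0, 0/1, 1/1 or ./. following
#' the package's 0/1/2/NA call coding. Re-reading the file with
#' [readGenotypeVCF()] reproduces the call matrix exactly.
#'
#' @param x GenotypeMatrix (typically one row per consensus individual).
#' @param metadata SNP metadata covering every locus in \code{x}; its
#'   optional \code{chrom} column supplies CHROM (default: the locus id)
#'   and \code{snp_position} supplies POS (default 1).
#' @param path output file path.
#' @export
writeConsensusVCF <- function(x, metadata, path) {
    loci <- locusIds(x)
    idx <- match(loci, metadata$locus_id)
    if (anyNA(idx))
        stop("loci absent from metadata: ",
             paste(loci[is.na(idx)], collapse = ", "))
    chrom <- if (!is.null(metadata$chrom)) metadata$chrom[idx] else loci
    pos <- if (!is.null(metadata$snp_position)) {
        p <- metadata$snp_position[idx]
        ifelse(is.na(p), 1L, as.integer(p))
    } else rep(1L, length(loci))
    gtmap <- c("0/0", "0/1", "1/1")
    g <- genotypeCalls(x)
    gt <- matrix("./.", nrow = length(loci), ncol = nrow(g))
    for (i in seq_len(nrow(g))) {
        called <- !is.na(g[i, ])
        gt[called, i] <- gtmap[g[i, called] + 1L]
    }
    header <- c("##fileformat=VCFv4.2",
                "##source=scatID",
                paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                       "Description=\"Genotype\">"),
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sampleIds(x)),
                      collapse = "\t"))
    body <- paste(chrom, pos, loci,
                  toupper(metadata$ref_allele[idx]),
                  toupper(metadata$alt_allele[idx]),
                  ".", ".", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read genotypes back from a biallelic VCF
#'
#' Uses \pkg{VariantAnnotation} to parse the file and converts diploid GT
#' fields to the package's 0/1/2/NA coding.
#'
#' @param path VCF file path.
#' @return a [GenotypeMatrix-class] (samples x loci).
#' @export
readGenotypeVCF <- function(path) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("readGenotypeVCF requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    code[gt %in% c("0/0", "0|0")] <- 0L
    code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    code[gt %in% c("1/1", "1|1")] <- 2L
    GenotypeMatrix(t(code))
}
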