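## Molecular sexing from endpoint qPCR RFU signals on two Y-linked
## markers (DDX3Y, SRY; Zfy optional) and the X-linked control Zfx.

SEX_MARKERS <- c("DDX3Y", "SRY", "Zfy", "Zfx")
Y_MARKERS <- c("DDX3Y", "SRY", "Zfy")
RFU_SUCCESS <- 50
Y_TO_X_MIN <- 0.1

#' Sex call for a single sample from its qPCR RFU signals
#'
#' A marker amplification is successful when its RFU signal is >= 50.
#' The sample is called male when the X-linked control (Zfx) succeeds, at
#' least one Y-linked marker succeeds, and the ratio of the strongest
#' Y-marker signal to the Zfx signal exceeds 0.1; female when Zfx
#' succeeds without such Y evidence; and no_call when the X control
#' fails. A Y signal without any Zfx signal is flagged as possible
#' contamination and yields no_call.
#'
#' @param rfu data.frame with columns \code{marker} and \code{rfu} for one
#'   sample (see [readRFUTable()]); must include Zfx. Zfy is used when
#'   present but never required.
#' @return one-row data.frame: sample_id (if present), per-marker success
#'   flags, y_to_x_ratio, call in \{male, female, no_call\}.
#' @export
callSampleSex <- function(rfu) {
    bad <- setdiff(unique(rfu$marker), SEX_MARKERS)
    if (length(bad))
        stop("unknown sex marker(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(rfu$marker))
        stop("duplicate marker records for one sample")
    sig <- stats::setNames(rep(NA_real_, length(SEX_MARKERS)), SEX_MARKERS)
    sig[rfu$marker] <- rfu$rfu
    if (is.na(sig["Zfx"]))
        stop("sexing requires the X-linked control marker Zfx")
    if (!any(!is.na(sig[Y_MARKERS])))
        stop("sexing requires at least one Y-linked marker (DDX3Y/SRY)")
    ok <- !is.na(sig) & sig >= RFU_SUCCESS
    ySig <- max(sig[Y_MARKERS], na.rm = TRUE)
    ratio <- if (sig["Zfx"] > 0) ySig / sig["Zfx"] else Inf
    contamination <- FALSE
    if (!ok["Zfx"]) {
        if (sig["Zfx"] == 0 && any(ok[Y_MARKERS])) {
            contamination <- TRUE
            warning("Y signal without Zfx amplification: ",
                    "possible contamination")
        }
        call <- "no_call"
    } else if (any(ok[Y_MARKERS]) && ratio > Y_TO_X_MIN) {
        call <- "male"
    } else {
        call <- "female"
    }
    out <- data.frame(DDX3Y_ok = unname(ok["DDX3Y"]),
                      SRY_ok = unname(ok["SRY"]),
                      Zfy_ok = unname(ok["Zfy"]),
                      Zfx_ok = unname(ok["Zfx"]),
                      y_to_x_ratio = if (is.finite(ratio)) unname(ratio)
                                     else NA_real_,
                      call = call, contamination = contamination)
    if (!is.null(rfu$sample_id))
        out <- cbind(data.frame(sample_id = rfu$sample_id[1L]), out)
    out
}

#' Sex calls for every sample in an RFU table
#'
#' @param rfu data.frame with columns sample_id, marker, rfu.
#' @return data.frame with one row per sample (see [callSampleSex()]).
#' @export
callSampleSexTable <- function(rfu) {
    out <- lapply(split(rfu, rfu$sample_id), callSampleSex)
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Individual-level sex from multiple sample calls
#'
#' Confirmed sex requires at least two successful sample calls that all
#' agree; a single successful call, or a strict majority with minor
#' disagreement, gives a "likely" sex; no successful call or a tie gives
#' undetermined.
#'
#' @param calls character vector of per-sample calls
#'   (male/female/no_call) for one individual.
#' @param maxSamples how many sample calls to use (default 3, the assay's
#'   per-individual budget); extra calls beyond this are ignored.
#' @return one of male, female, likely_male, likely_female, undetermined.
#' @export
callIndividualSex <- function(calls, maxSamples = 3) {
    stopifnot(length(calls) >= 1L)
    calls <- utils::head(calls, maxSamples)
    nm <- sum(calls == "male")
    nf <- sum(calls == "female")
    if (nm + nf == 0L) return("undetermined")
    if (nf == 0L) return(if (nm >= 2L) "male" else "likely_male")
    if (nm == 0L) return(if (nf >= 2L) "female" else "likely_female")
    if (nm > nf) return("likely_male")
    if (nf > nm) return("likely_female")
    "undetermined"
}

#' Individual sex table for a clustering
#'
#' Joins per-sample sex calls onto a scat-to-individual assignment and
#' derives each individual's sex category.
#'
#' @param sampleCalls data.frame from [callSampleSexTable()].
#' @param assignment a [GroupAssignment-class]; samples missing from the
#'   RFU table are ignored.
#' @param maxSamples per-individual sample budget (default 3).
#' @return data.frame: group, category, n_samples, calls (collapsed).
#' @export
individualSexTable <- function(sampleCalls, assignment, maxSamples = 3) {
    gid <- groupMembership(assignment)
    use <- sampleCalls[sampleCalls$sample_id %in% names(gid), ]
    grp <- gid[use$sample_id]
    out <- lapply(split(use$call, grp), function(cc)
        data.frame(category = callIndividualSex(cc, maxSamples),
                   n_samples = length(cc),
                   calls = paste(cc, collapse = ";")))
    res <- do.call(rbind, out)
    cbind(data.frame(group = as.integer(rownames(res))), res,
          row.names = NULL)
}

#' Male-to-female sex ratio
#'
#' @param categories character vector of individual sex categories
#'   (male, female, likely_male, likely_female, undetermined).
#' @param includeLikely also count likely_male/likely_female (default
#'   FALSE). Undetermined individuals are always excluded.
#' @return males per female, rounded to one decimal; NA with a warning
#'   when no females are counted.
#' @examples
#' sexRatio(c(rep("male", 8), rep("female", 5)))            # 1.6
#' sexRatio(c(rep("male", 8), "likely_male", rep("female", 5),
#'            rep("likely_female", 5)), includeLikely = TRUE) # 0.9
#' @export
sexRatio <- function(categories, includeLikely = FALSE) {
    males <- sum(categories == "male")
    females <- sum(categories == "female")
    if (includeLikely) {
        males <- males + sum(categories == "likely_male")
        females <- females + sum(categories == "likely_female")
    }
    if (females == 0L) {
        warning("sex ratio undefined: no females counted")
        return(NA_real_)
    }
    round(males / females, 1)
}
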