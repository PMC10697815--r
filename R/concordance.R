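## Short-read vs long-read CNV concordance.
##
## Samples failing the 30-Gbp molecular-yield QC are excluded entirely;
## per (CNV, sample) the classification is not_assessable when the
## regional long-read coverage is below `coverage_min`, concordant when
## both technologies indicate the same CN direction (both below 2, both
## above 2, or wild type with no overlapping long-read CNV call), and
## discordant otherwise.  Short-read deletions match DEL records;
## duplications match DUP records and, optionally, insertion records
## (long-read callers report tandem-repeat CN gains as insertion
## clusters).

#' Long-read sample yield QC
#'
#' @param yields named numeric vector of unique molecular yields in Gbp.
#' @param min_yield inclusive lower bound for passing (yields strictly
#'   below are excluded; 30 Gbp corresponds to about 10x coverage).
#' @return data.frame `sample_id`, `yield_gbp`, `passed`.
#' @export
coverageQc <- function(yields, min_yield = 30) {
    stopifnot(all(yields >= 0))
    data.frame(sample_id = names(yields), yield_gbp = as.numeric(yields),
               passed = as.numeric(yields) >= min_yield,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Reciprocal overlap of two intervals
#'
#' `min(overlap/|a|, overlap/|b|)`; 0 for intervals on different
#' chromosomes or disjoint intervals.  Symmetric, and non-increasing as
#' either interval grows away from the other.
#'
#' @param a,b `GRanges` of equal length (recycled if one has length 1).
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
reciprocalOverlap <- function(a, b) {
    n <- max(length(a), length(b))
    a <- rep(a, length.out = n)
    b <- rep(b, length.out = n)
    same <- as.character(GenomeInfoDb::seqnames(a)) ==
        as.character(GenomeInfoDb::seqnames(b))
    ov <- pmax(pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
                   pmax(GenomicRanges::start(a),
                        GenomicRanges::start(b)) + 1, 0)
    out <- ifelse(same,
                  pmin(ov / GenomicRanges::width(a),
                       ov / GenomicRanges::width(b)), 0)
    as.numeric(out)
}

.consistent_types <- function(short_type, ins_as_dup = TRUE) {
    if (short_type == "deletion") return("DEL")
    if (ins_as_dup) c("DUP", "INS") else "DUP"
}

#' Match a short-read call against a sample's long-read SV records
#'
#' In `reciprocal_50` mode a long-read record matches when its reciprocal
#' overlap with the short-read call is at least 0.5 and its type implies a
#' consistent CN change (deletion vs DEL; duplication vs DUP, or INS when
#' `ins_as_dup`).  In `any_1bp` mode a 1-bp overlap suffices under the
#' same consistency rule.  INV and BND records are never consistent.
#'
#' @param short_call `GRanges` (length 1) of the short-read call/CNV.
#' @param short_type `"deletion"` or `"duplication"`.
#' @param long_records `GRanges` of the sample's SV records
#'   ([readSvVcf()] layout).
#' @param mode `"reciprocal_50"` or `"any_1bp"`.
#' @param ins_as_dup treat insertions as duplication-consistent.
#' @return the matching subset of `long_records`.
#' @export
matchCalls <- function(short_call, short_type, long_records,
                       mode = c("reciprocal_50", "any_1bp"),
                       ins_as_dup = TRUE) {
    mode <- match.arg(mode)
    if (length(long_records) == 0) return(long_records)
    types <- .consistent_types(short_type, ins_as_dup)
    cand <- long_records[mcols(long_records)$sv_type %in% types]
    if (length(cand) == 0) return(cand)
    if (mode == "reciprocal_50") {
        ro <- reciprocalOverlap(rep(short_call, length(cand)), cand)
        cand[ro >= 0.5]
    } else {
        cand[GenomicRanges::countOverlaps(cand, short_call) > 0]
    }
}

#' Classify short-read vs long-read concordance per (CNV, sample)
#'
#' @param cnm merged [CNMatrix-class] restricted to the long-read
#'   subcohort samples (columns).
#' @param long_records `GRanges` of all samples' long-read SV records.
#' @param yields named yields vector (Gbp) for the subcohort.
#' @param coverage CNVs x samples matrix of regional long-read coverage,
#'   rows aligned with `cnm`.
#' @param coverage_min regional coverage below which a cell is
#'   not_assessable.
#' @param mode,ins_as_dup passed to [matchCalls()].
#' @return data.frame with one row per (CNV, sample passing yield QC):
#'   `cnv_idx`, `sample_id`, `short_cn`, `short_state` (`deletion`,
#'   `duplication`, `wildtype`, `missing`), `long_state` (`deletion`,
#'   `duplication`, `none`, `low_coverage`), `classification`
#'   (`concordant`, `discordant`, `not_assessable`).  Samples failing the
#'   yield QC are omitted; cells with `short_state == "missing"` are
#'   classified `not_assessable`.
#' @export
classifyConcordance <- function(cnm, long_records, yields, coverage,
                                coverage_min = 5,
                                mode = c("reciprocal_50", "any_1bp"),
                                ins_as_dup = TRUE) {
    mode <- match.arg(mode)
    qc <- coverageQc(yields)
    pass_ids <- qc$sample_id[qc$passed]
    pass_ids <- intersect(colnames(cnValues(cnm)), pass_ids)
    cn <- cnValues(cnm)
    rr <- rowRanges(cnm)
    cnv_chrom <- as.character(GenomeInfoDb::seqnames(rr))
    cnv_start <- GenomicRanges::start(rr)
    cnv_end <- GenomicRanges::end(rr)
    lrd <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(long_records)),
        start = GenomicRanges::start(long_records),
        end = GenomicRanges::end(long_records),
        sample_id = if (length(long_records) > 0)
            mcols(long_records)$sample_id else character(0),
        sv_type = if (length(long_records) > 0)
            mcols(long_records)$sv_type else character(0),
        genotype = if (length(long_records) > 0)
            mcols(long_records)$genotype else character(0),
        stringsAsFactors = FALSE)
    lr_by_sample <- split(seq_len(nrow(lrd)), lrd$sample_id)
    n_out <- nrow(cn) * length(pass_ids)
    out <- data.frame(cnv_idx = integer(n_out),
                      sample_id = character(n_out),
                      short_cn = numeric(n_out),
                      short_state = character(n_out),
                      long_state = character(n_out),
                      classification = character(n_out),
                      stringsAsFactors = FALSE)
    k <- 0L
    for (s in pass_ids) {
        ridx <- lr_by_sample[[s]]
        sl <- if (is.null(ridx)) lrd[0, , drop = FALSE] else
            lrd[ridx, , drop = FALSE]
        for (i in seq_len(nrow(cn))) {
            v <- cn[i, s]
            short_state <- if (is.na(v)) "missing" else
                if (v < 2 - 1e-9) "deletion" else
                    if (v > 2 + 1e-9) "duplication" else "wildtype"
            cov <- coverage[i, s]
            ov <- pmin(sl$end, cnv_end[i]) -
                pmax(sl$start, cnv_start[i]) + 1
            ov[sl$chrom != cnv_chrom[i]] <- 0
            if (cov < coverage_min) {
                long_state <- "low_coverage"
                cls <- "not_assessable"
            } else if (short_state == "missing") {
                long_state <- "none"
                cls <- "not_assessable"
            } else if (short_state == "wildtype") {
                ## any overlapping CNV-type long-read call contradicts WT
                types <- c("DEL", "DUP", if (ins_as_dup) "INS")
                hit <- which(ov > 0 & sl$sv_type %in% types &
                                 sl$genotype != "hom_ref")
                long_state <- if (length(hit) == 0) "none" else
                    if (sl$sv_type[hit[1]] == "DEL") "deletion"
                    else "duplication"
                cls <- if (length(hit) > 0) "discordant" else "concordant"
            } else {
                types <- .consistent_types(short_state, ins_as_dup)
                cand <- which(ov > 0 & sl$sv_type %in% types)
                if (mode == "reciprocal_50" && length(cand) > 0) {
                    ro <- pmin(
                        ov[cand] / (sl$end[cand] - sl$start[cand] + 1),
                        ov[cand] / (cnv_end[i] - cnv_start[i] + 1))
                    cand <- cand[ro >= 0.5]
                }
                matched <- length(cand) > 0
                long_state <- if (matched) short_state else "none"
                cls <- if (matched) "concordant" else "discordant"
            }
            k <- k + 1L
            out$cnv_idx[k] <- i
            out$sample_id[k] <- s
            out$short_cn[k] <- v
            out$short_state[k] <- short_state
            out$long_state[k] <- long_state
            out$classification[k] <- cls
        }
    }
    out[seq_len(k), , drop = FALSE]
}

#' Per-CNV validation summary
#'
#' Tabulates, per CNV and per short-read carrier direction, the numbers of
#' concordant, discordant and not-assessable individuals, mirroring a
#' short-vs-long-read comparison table, and flags a CNV `validated_100`
#' when no carrier is discordant and at least one carrier was assessable.
#'
#' @param records output of [classifyConcordance()].
#' @return data.frame, one row per CNV: `cnv_idx`, `n_del_carriers`,
#'   `del_concordant`, `del_discordant`, `del_na`, `n_dup_carriers`,
#'   `dup_concordant`, `dup_discordant`, `dup_na`, `wt_discordant`,
#'   `validated_100`.
#' @export
summarizeValidation <- function(records) {
    do.call(rbind, lapply(split(records, records$cnv_idx), function(r) {
        del <- r[r$short_state == "deletion", ]
        dup <- r[r$short_state == "duplication", ]
        wt <- r[r$short_state == "wildtype", ]
        carriers <- rbind(del, dup)
        assessed <- sum(carriers$classification != "not_assessable")
        data.frame(
            cnv_idx = r$cnv_idx[1],
            n_del_carriers = nrow(del),
            del_concordant = sum(del$classification == "concordant"),
            del_discordant = sum(del$classification == "discordant"),
            del_na = sum(del$classification == "not_assessable"),
            n_dup_carriers = nrow(dup),
            dup_concordant = sum(dup$classification == "concordant"),
            dup_discordant = sum(dup$classification == "discordant"),
            dup_na = sum(dup$classification == "not_assessable"),
            wt_discordant = sum(wt$classification == "discordant"),
            validated_100 =
                sum(carriers$classification == "discordant") == 0 &&
                assessed >= 1)
    }))
}
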