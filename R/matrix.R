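## Population CN matrix.
##
## Discovery calls pass a strict two-tier QC: a per-call Bonferroni bound
## (family-wise alpha over samples x per-sample calls) plus the q0
## alignment-quality filter define the high-confidence tier used to select
## 200-bp genome windows; genotyping of the selected windows then applies
## only the q0 filter (the lenient tier), fills non-carriers with CN 2 and
## marks samples whose only overlapping calls failed q0 as missing.

#' Strict-tier QC of discovery calls
#'
#' A call is retained iff its t-test p-value is below
#' `alpha / (n_samples x m_s)`, where `m_s` is the number of calls in that
#' call's sample (Bonferroni over the whole discovery set), and its q0 is
#' below `q0_max`.
#'
#' @param calls `GRanges` of calls ([readCnvCalls()] layout).
#' @param n_samples number of samples in the cohort (not just samples with
#'   calls).
#' @param alpha family-wise significance level.
#' @param q0_max exclusive upper bound on q0 for retention (calls with
#'   q0 >= `q0_max` are removed).
#' @return the retained subset of `calls`.
#' @export
qcHighConfidence <- function(calls, n_samples, alpha = 0.05,
                             q0_max = 0.5) {
    if (length(calls) == 0) return(calls)
    m_s <- table(mcols(calls)$sample_id)
    thr <- alpha / (n_samples * as.numeric(m_s[mcols(calls)$sample_id]))
    keep <- mcols(calls)$p_value < thr & mcols(calls)$q0 < q0_max
    calls[keep]
}

#' Tile the genome into non-overlapping windows
#'
#' @param chromosome_lengths named numeric vector of chromosome lengths.
#' @param window_size window width in bp (200 for the CN matrix).
#' @return `GRanges` of `ceiling(L / window_size)` windows per chromosome,
#'   ordered by (chrom, start); the terminal window is truncated to the
#'   chromosome end.
#' @export
buildWindowGrid <- function(chromosome_lengths, window_size = 200) {
    stopifnot(all(chromosome_lengths > 0))
    sl <- chromosome_lengths[order(names(chromosome_lengths))]
    GenomicRanges::tileGenome(sl, tilewidth = window_size,
                              cut.last.tile.in.chrom = TRUE)
}

#' Select the windows touched by any high-confidence call
#'
#' @param hc_calls high-confidence calls (output of [qcHighConfidence()]).
#' @param grid window grid from [buildWindowGrid()].
#' @return the subset of `grid` overlapped by >= 1 bp by >= 1 call.
#' @export
selectWindows <- function(hc_calls, grid) {
    grid[GenomicRanges::countOverlaps(grid, hc_calls) > 0]
}

#' Genotype selected windows across the cohort
#'
#' For each (sample, window) cell: if a lenient-tier call (q0 < `q0_max`)
#' overlaps the window, the cell takes that call's CN (provenance
#' `"called"`); if the sample's only overlapping calls failed the q0
#' filter, the cell is missing (`"failed_qc"`); otherwise the sample is
#' wild type and the cell is exactly 2 (`"wildtype_fill"`).  When several
#' lenient calls overlap one window for one sample the call with the
#' largest bp overlap wins, ties broken by the smaller call start.
#'
#' @param calls all discovery calls (pre-QC) for the cohort.
#' @param windows the selected windows (from [selectWindows()]).
#' @param sample_ids full cohort sample identifiers (samples without any
#'   call are genotyped wild type everywhere).
#' @param q0_max the lenient-tier q0 bound.
#' @return a [CNMatrix-class], rows following `windows`.
#' @export
genotypeWindows <- function(calls, windows, sample_ids, q0_max = 0.5) {
    windows <- GenomicRanges::sort(windows)
    nw <- length(windows)
    ns <- length(sample_ids)
    cn <- matrix(2, nw, ns, dimnames = list(NULL, sample_ids))
    prov <- matrix("wildtype_fill", nw, ns,
                   dimnames = list(NULL, sample_ids))
    if (length(calls) > 0 && nw > 0) {
        hits <- GenomicRanges::findOverlaps(windows, calls)
        if (length(hits) > 0) {
            wi <- queryHits(hits)
            ci <- subjectHits(hits)
            ov <- GenomicRanges::width(IRanges::pintersect(
                GenomicRanges::ranges(windows)[wi],
                GenomicRanges::ranges(calls)[ci]))
            si <- match(mcols(calls)$sample_id[ci], sample_ids)
            lenient <- mcols(calls)$q0[ci] < q0_max
            keep <- !is.na(si)
            df <- data.frame(wi = wi[keep], si = si[keep], ov = ov[keep],
                             cs = GenomicRanges::start(calls)[ci[keep]],
                             cn = mcols(calls)$cn[ci[keep]],
                             lenient = lenient[keep])
            len <- df[df$lenient, , drop = FALSE]
            if (nrow(len) > 0) {
                o <- order(len$wi, len$si, -len$ov, len$cs)
                len <- len[o, , drop = FALSE]
                first <- !duplicated(len[, c("wi", "si")])
                win <- len[first, , drop = FALSE]
                idx <- cbind(win$wi, win$si)
                cn[idx] <- win$cn
                prov[idx] <- "called"
            }
            fail <- df[!df$lenient, , drop = FALSE]
            if (nrow(fail) > 0) {
                idx <- cbind(fail$wi, fail$si)
                only_failed <- prov[idx] == "wildtype_fill"
                if (any(only_failed)) {
                    idx <- idx[only_failed, , drop = FALSE]
                    cn[idx] <- NA
                    prov[idx] <- "failed_qc"
                }
            }
        }
    }
    CNMatrix(cn, prov, windows, sample_ids)
}

.rows_identical <- function(a, b) {
    all((a == b) | (is.na(a) & is.na(b)), na.rm = FALSE) %in% TRUE
}

#' Merge adjacent windows with identical CN columns
#'
#' Maximal runs of grid-adjacent windows (same chromosome, next start
#' exactly one past the previous end) whose per-sample CN vectors are
#' element-wise identical (missing matches only missing) are merged into
#' one CNV; exact equality is used because the values within one call are
#' bit-identical across its windows.  Non-adjacent windows never merge.
#' The operation is idempotent.
#'
#' @param cnm a [CNMatrix-class] of genotyped windows.
#' @return a [CNMatrix-class] with one row per merged CNV; row ranges are
#'   the union interval and carry metadata columns `n_windows` and
#'   `members` (an [IRanges::IntegerList] of member row indices of the
#'   input).
#' @export
mergeAdjacent <- function(cnm) {
    nw <- nrow(cnm)
    if (nw == 0) return(cnm)
    rr <- rowRanges(cnm)
    o <- GenomicRanges::order(rr)
    rr <- rr[o]
    cn <- cnValues(cnm)[o, , drop = FALSE]
    prov <- cnProvenance(cnm)[o, , drop = FALSE]
    chrom <- as.character(GenomeInfoDb::seqnames(rr))
    starts <- GenomicRanges::start(rr)
    ends <- GenomicRanges::end(rr)
    grp <- integer(nw)
    grp[1] <- 1L
    for (i in seq_len(nw - 1)) {
        adjacent <- chrom[i + 1] == chrom[i] &&
            starts[i + 1] == ends[i] + 1
        same <- adjacent && .rows_identical(cn[i, ], cn[i + 1, ])
        grp[i + 1] <- if (same) grp[i] else grp[i] + 1L
    }
    ng <- grp[nw]
    first <- match(seq_len(ng), grp)
    members <- split(seq_len(nw), grp)
    merged_rr <- GenomicRanges::GRanges(
        chrom[first],
        IRanges::IRanges(
            vapply(members, function(m) min(starts[m]), 0),
            vapply(members, function(m) max(ends[m]), 0)),
        seqinfo = GenomeInfoDb::seqinfo(rr))
    mcols(merged_rr)$n_windows <- unname(lengths(members))
    mcols(merged_rr)$members <- IRanges::IntegerList(unname(members))
    CNMatrix(cn[first, , drop = FALSE], prov[first, , drop = FALSE],
             merged_rr, colnames(cn))
}

#' Build the merged population CN matrix from discovery calls
#'
#' Convenience wrapper chaining [qcHighConfidence()], [buildWindowGrid()],
#' [selectWindows()], [genotypeWindows()] and [mergeAdjacent()].
#'
#' @param calls all discovery calls for the cohort.
#' @param chromosome_lengths named chromosome-length vector.
#' @param sample_ids cohort sample identifiers.
#' @param alpha,q0_max strict-tier QC thresholds.
#' @param window_size window width in bp.
#' @return list with `windows` (the per-window [CNMatrix-class]) and
#'   `merged` (the merged one).
#' @export
buildCnMatrix <- function(calls, chromosome_lengths, sample_ids,
                          alpha = 0.05, q0_max = 0.5, window_size = 200) {
    hc <- qcHighConfidence(calls, length(sample_ids), alpha, q0_max)
    grid <- buildWindowGrid(chromosome_lengths, window_size)
    sel <- selectWindows(hc, grid)
    wins <- genotypeWindows(calls, sel, sample_ids, q0_max)
    list(windows = wins, merged = mergeAdjacent(wins))
}
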