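## Post-association clumping and conditioning.
##
## Significant windows on one chromosome whose CN vectors are strongly
## correlated (squared Spearman R^2 > 0.8) are grouped under the window
## with the smallest p-value (the lead); windows with R^2 < 0.1 to every
## lead are independent signals.  Windows falling in between are not
## silently assigned: they seed their own clumps and are flagged
## `correlated_unresolved` against the nearest lead.

#' Squared Spearman rank correlation
#'
#' @param x,y numeric vectors; pairs with a missing value are dropped.
#' @return R^2 in `[0, 1]` (average ranks for ties), or `NA` when fewer
#'   than 3 complete pairs remain or either vector is constant.
#' @export
spearmanR2 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(NA_real_)
    xs <- x[ok]; ys <- y[ok]
    if (length(unique(xs)) < 2 || length(unique(ys)) < 2) return(NA_real_)
    stats::cor(xs, ys, method = "spearman")^2
}

#' Clump correlated significant windows into independent signals
#'
#' Greedy clumping per protein: repeatedly take the unassigned window with
#' the smallest p-value (ties: smaller start) as a lead and assign every
#' unassigned same-chromosome window with R^2 > `r2_member` to it.
#' Windows whose R^2 to every existing lead lies in
#' `[r2_independent, r2_member]` eventually lead their own clumps but are
#' flagged `correlated_unresolved` with the identity of the nearest such
#' lead; windows with R^2 < `r2_independent` to all leads are independent.
#'
#' @param windows `GRanges` of the significant windows (one protein's, or
#'   carrying a `protein_id` metadata column to clump per protein).
#' @param p p-values aligned with `windows`.
#' @param cn windows x samples CN matrix aligned with `windows`.
#' @param protein_id optional per-window protein labels (defaults to the
#'   `protein_id` metadata column, or a single group).
#' @param r2_member membership threshold (R^2 above this joins the lead).
#' @param r2_independent independence threshold (R^2 below this to every
#'   lead marks an independent signal).
#' @return data.frame with one row per window: `window_idx`, `protein_id`,
#'   `clump_id`, `lead` (logical), `lead_idx`, `r2_to_lead`,
#'   `correlated_unresolved`, `unresolved_against`.
#' @export
clumpWindows <- function(windows, p, cn, protein_id = NULL,
                         r2_member = 0.8, r2_independent = 0.1) {
    n <- length(windows)
    stopifnot(length(p) == n, nrow(cn) == n)
    if (is.null(protein_id)) {
        protein_id <- if (!is.null(mcols(windows)$protein_id))
            mcols(windows)$protein_id else rep("all", n)
    }
    chrom <- as.character(GenomeInfoDb::seqnames(windows))
    starts <- GenomicRanges::start(windows)
    out <- data.frame(window_idx = seq_len(n), protein_id = protein_id,
                      clump_id = NA_integer_, lead = FALSE,
                      lead_idx = NA_integer_, r2_to_lead = NA_real_,
                      correlated_unresolved = FALSE,
                      unresolved_against = NA_integer_,
                      stringsAsFactors = FALSE)
    next_clump <- 0L
    for (prot in unique(protein_id)) {
        sel <- which(protein_id == prot)
        unassigned <- sel
        leads <- integer(0)
        ## dead-zone bookkeeping: nearest lead with intermediate R^2
        dead_against <- setNames(rep(NA_integer_, length(sel)), sel)
        while (length(unassigned) > 0) {
            o <- order(p[unassigned], starts[unassigned])
            lead <- unassigned[o[1]]
            next_clump <- next_clump + 1L
            out$clump_id[lead] <- next_clump
            out$lead[lead] <- TRUE
            out$lead_idx[lead] <- lead
            out$r2_to_lead[lead] <- 1
            if (!is.na(dead_against[as.character(lead)])) {
                out$correlated_unresolved[lead] <- TRUE
                out$unresolved_against[lead] <-
                    dead_against[as.character(lead)]
            }
            leads <- c(leads, lead)
            unassigned <- setdiff(unassigned, lead)
            if (length(unassigned) == 0) break
            same <- unassigned[chrom[unassigned] == chrom[lead]]
            if (length(same) > 0) {
                r2 <- vapply(same, function(w)
                    spearmanR2(cn[lead, ], cn[w, ]), 0)
                member <- same[!is.na(r2) & r2 > r2_member]
                if (length(member) > 0) {
                    out$clump_id[member] <- next_clump
                    out$lead_idx[member] <- lead
                    out$r2_to_lead[member] <-
                        r2[match(member, same)]
                    unassigned <- setdiff(unassigned, member)
                }
                dead <- same[!is.na(r2) & r2 >= r2_independent &
                                 r2 <= r2_member]
                for (w in dead) {
                    prev <- dead_against[as.character(w)]
                    if (is.na(prev) ||
                        abs(starts[w] - starts[lead]) <
                            abs(starts[w] - starts[prev]))
                        dead_against[as.character(w)] <- lead
                }
            }
        }
    }
    out
}

#' Summarize clumps (span, lead coordinates)
#'
#' @param clumps output of [clumpWindows()].
#' @param windows the `GRanges` passed to [clumpWindows()].
#' @param p the p-values passed to [clumpWindows()].
#' @return data.frame, one row per clump: `clump_id`, `protein_id`,
#'   `chrom`, `span_start`, `span_end`, `lead_idx`, `lead_start`,
#'   `lead_p`, `n_members`, `correlated_unresolved`.
#' @export
summarizeClumps <- function(clumps, windows, p) {
    chrom <- as.character(GenomeInfoDb::seqnames(windows))
    starts <- GenomicRanges::start(windows)
    ends <- GenomicRanges::end(windows)
    do.call(rbind, lapply(split(clumps, clumps$clump_id), function(cl) {
        lead <- cl$window_idx[cl$lead]
        data.frame(clump_id = cl$clump_id[1],
                   protein_id = cl$protein_id[1],
                   chrom = chrom[lead],
                   span_start = min(starts[cl$window_idx]),
                   span_end = max(ends[cl$window_idx]),
                   lead_idx = lead, lead_start = starts[lead],
                   lead_p = p[lead], n_members = nrow(cl),
                   correlated_unresolved =
                       any(cl$correlated_unresolved),
                   stringsAsFactors = FALSE)
    }))
}

#' Find prior GWAS hits overlapping a clump
#'
#' A SNP hit is a candidate overlap when it concerns the same protein,
#' reaches genome-wide significance (p < `p_max`), and lies within
#' `max_dist` bp of the clump span (distance 0 if inside).
#'
#' @param clump_span `GRanges` (length 1) of the clump's union interval.
#' @param clump_protein the clump's protein identifier.
#' @param gwas data.frame with columns `snp_id`, `chrom`, `position`,
#'   `protein_id`, `p_value`.
#' @param p_max GWAS significance bound.
#' @param max_dist distance bound in bp.
#' @return the qualifying subset of `gwas`.
#' @export
overlapGwas <- function(clump_span, clump_protein, gwas,
                        p_max = 5e-8, max_dist = 1e6) {
    if (nrow(gwas) == 0) return(gwas[0, , drop = FALSE])
    same_prot <- gwas$protein_id == clump_protein
    sig <- gwas$p_value < p_max
    same_chrom <- as.character(gwas$chrom) ==
        as.character(GenomeInfoDb::seqnames(clump_span))[1]
    s <- GenomicRanges::start(clump_span)[1]
    e <- GenomicRanges::end(clump_span)[1]
    d <- ifelse(gwas$position < s, s - gwas$position,
                ifelse(gwas$position > e, gwas$position - e, 0))
    gwas[same_prot & sig & same_chrom & d < max_dist, , drop = FALSE]
}

#' Conditional association fit adjusting for overlapping SNPs
#'
#' Refits the association model with the SNP allele counts added as
#' covariates and reports whether the CN coefficient retains significance
#' at the study threshold.
#'
#' @param cn,y,pcs,n_pcs as in [fitAssociation()].
#' @param snps samples x SNPs matrix of allele counts (>= 1 column).
#' @param threshold the study significance threshold used for the
#'   `retains_significance` flag.
#' @return one-row data.frame: the [fitAssociation()] columns plus
#'   `retains_significance`.
#' @export
conditionalFit <- function(cn, y, pcs = NULL, n_pcs = NULL, snps,
                           threshold = NULL) {
    snps <- as.matrix(snps)
    stopifnot(ncol(snps) >= 1)
    use <- !is.na(cn) & stats::complete.cases(snps)
    r2 <- suppressWarnings(summary(
        stats::lm(cn[use] ~ snps[use, , drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12)
        stop("collinear conditioning: SNP(s) explain the CN exactly")
    rec <- fitAssociation(cn, y, pcs, n_pcs, extra = snps)
    rec$retains_significance <- if (is.null(threshold)) NA else
        rec$p_value < threshold
    rec
}

#' Repeat annotation of a clump span
#'
#' @param span `GRanges` of one or more spans.
#' @param repeats `GRanges` of repeat intervals (e.g. a RepeatMasker BED
#'   via [readBed()]).
#' @return data.frame: `span_idx`, `repeat_idx`, `repeat_name` (from the
#'   `name` metadata column when present), `overlap_bp`.
#' @export
annotateRepeats <- function(span, repeats) {
    hits <- GenomicRanges::findOverlaps(span, repeats)
    if (length(hits) == 0)
        return(data.frame(span_idx = integer(0), repeat_idx = integer(0),
                          repeat_name = character(0),
                          overlap_bp = integer(0)))
    ov <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(span)[queryHits(hits)],
        GenomicRanges::ranges(repeats)[subjectHits(hits)]))
    nm <- if (!is.null(mcols(repeats)$name))
        as.character(mcols(repeats)$name)[subjectHits(hits)]
    else NA_character_
    data.frame(span_idx = queryHits(hits),
               repeat_idx = subjectHits(hits),
               repeat_name = nm, overlap_bp = ov,
               stringsAsFactors = FALSE)
}
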