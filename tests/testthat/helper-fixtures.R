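## Fixture builders and independent brute-force oracles used across tests.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

## Build a calls GRanges from a plain data.frame with columns
## sample_id, sv_type, chrom, start, end, cn, p_value, q0.
makeCalls <- function(df) {
    gr <- GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    mcols(gr)$sample_id <- df$sample_id
    mcols(gr)$sv_type <- df$sv_type
    mcols(gr)$cn <- df$cn
    mcols(gr)$p_value <- df$p_value
    mcols(gr)$q0 <- df$q0
    gr
}

## Hand-built matrix-stage fixture: one 1000-bp chromosome (5 windows of
## 200 bp), 4 samples, calls exercising both QC tiers, wild-type fill,
## failed-q0 missingness and adjacent-window merging.
matrixFixture <- function() {
    calls <- data.frame(
        sample_id = c("s1", "s2", "s3", "s4", "s2"),
        sv_type = c("deletion", "deletion", "deletion", "deletion",
                    "duplication"),
        chrom = "1",
        start = c(101, 101, 201, 801, 801),
        end = c(600, 600, 600, 1000, 1000),
        cn = c(1.02, 0.98, 1.10, 1.30, 2.60),
        p_value = c(1e-9, 1e-8, 0.2, 1e-9, 1e-10),
        q0 = c(0.1, 0.1, 0.1, 0.7, 0.0),
        stringsAsFactors = FALSE)
    list(calls_df = calls, calls = makeCalls(calls),
         chrom_lengths = c(`1` = 1000),
         samples = c("s1", "s2", "s3", "s4"))
}

## --- Brute-force oracle for the matrix stage, written as direct loops
## over plain vectors (no interval machinery shared with the package). ---

bfOverlapBp <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2) + 1)

bfHighConfidence <- function(calls_df, n_samples, alpha = 0.05,
                             q0_max = 0.5) {
    m_s <- table(calls_df$sample_id)
    keep <- logical(nrow(calls_df))
    for (i in seq_len(nrow(calls_df))) {
        thr <- alpha / (n_samples * m_s[[calls_df$sample_id[i]]])
        keep[i] <- calls_df$p_value[i] < thr && calls_df$q0[i] < q0_max
    }
    calls_df[keep, , drop = FALSE]
}

bfWindows <- function(L, w = 200) {
    n <- ceiling(L / w)
    data.frame(start = (seq_len(n) - 1) * w + 1,
               end = pmin(seq_len(n) * w, L))
}

bfSelect <- function(hc, windows) {
    sel <- logical(nrow(windows))
    for (i in seq_len(nrow(windows)))
        for (j in seq_len(nrow(hc)))
            if (bfOverlapBp(windows$start[i], windows$end[i],
                            hc$start[j], hc$end[j]) > 0) sel[i] <- TRUE
    windows[sel, , drop = FALSE]
}

bfGenotype <- function(calls_df, sel, samples, q0_max = 0.5) {
    cn <- matrix(2, nrow(sel), length(samples),
                 dimnames = list(NULL, samples))
    prov <- matrix("wildtype_fill", nrow(sel), length(samples),
                   dimnames = list(NULL, samples))
    for (i in seq_len(nrow(sel))) {
        for (s in samples) {
            cs <- calls_df[calls_df$sample_id == s, , drop = FALSE]
            if (nrow(cs) == 0) next
            ov <- mapply(bfOverlapBp, sel$start[i], sel$end[i],
                         cs$start, cs$end)
            cs <- cs[ov > 0, , drop = FALSE]; ov <- ov[ov > 0]
            if (nrow(cs) == 0) next
            len <- cs$q0 < q0_max
            if (any(len)) {
                cl <- cs[len, , drop = FALSE]; ol <- ov[len]
                pick <- order(-ol, cl$start)[1]
                cn[i, s] <- cl$cn[pick]
                prov[i, s] <- "called"
            } else {
                cn[i, s] <- NA
                prov[i, s] <- "failed_qc"
            }
        }
    }
    list(cn = cn, prov = prov)
}

bfMerge <- function(sel, cn) {
    n <- nrow(sel)
    grp <- integer(n); grp[1] <- 1L
    for (i in seq_len(n - 1)) {
        adj <- sel$start[i + 1] == sel$end[i] + 1
        eq <- all((cn[i, ] == cn[i + 1, ]) |
                      (is.na(cn[i, ]) & is.na(cn[i + 1, ])), na.rm = FALSE)
        eq <- isTRUE(eq)
        grp[i + 1] <- if (adj && eq) grp[i] else grp[i] + 1L
    }
    out <- NULL
    for (g in unique(grp)) {
        m <- which(grp == g)
        out <- rbind(out, data.frame(start = min(sel$start[m]),
                                     end = max(sel$end[m]),
                                     n_windows = length(m),
                                     first = m[1]))
    }
    out
}
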