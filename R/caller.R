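## Read-depth CNV caller.
##
## Implements the per-sample caller statistics: optimal bin-size selection
## (smallest bin whose depth mean/SD ratio lies in [4, 5], balancing t-test
## power against breakpoint resolution), the real-valued CN estimate
## (2 x regional/global depth ratio), the one-sample t-test of regional
## bins against the global mean, and the depth-weighted q0 fraction.
## Segmentation of the binned profile into candidate calls uses a simple
## run-based thresholding of the depth ratio; the thresholds are exposed
## as arguments.

#' Bin a per-base depth (or q0) track
#'
#' Sums per-base depth into consecutive non-overlapping bins; an
#' incomplete terminal bin is dropped.  For q0 the depth-weighted per-bin
#' mean is returned instead.
#'
#' @param depth numeric vector of per-base read depth.
#' @param bin_size bin width in bp.
#' @param q0 optional per-base q0 fractions; when given, the return value
#'   is a list with `depth` (per-bin sums) and `q0` (depth-weighted per-bin
#'   means, 0 where a bin has zero depth).
#' @return numeric vector of per-bin depth sums, or a list (see `q0`).
#' @export
binDepth <- function(depth, bin_size, q0 = NULL) {
    nb <- length(depth) %/% bin_size
    idx <- seq_len(nb * bin_size)
    f <- rep(seq_len(nb), each = bin_size)
    sums <- as.numeric(rowsum(depth[idx], f))
    if (is.null(q0)) return(sums)
    wq <- as.numeric(rowsum(depth[idx] * q0[idx], f))
    q0b <- ifelse(sums > 0, wq / sums, 0)
    list(depth = sums, q0 = q0b)
}

#' Select the optimal read-depth bin size
#'
#' Chooses the smallest candidate bin size at which the ratio of the
#' binned depth mean to its standard deviation lies in `ratio_bounds`
#' (inclusive at both ends).  For Poisson per-base depth with rate lambda,
#' the binned mean/SD ratio is sqrt(bin_size x lambda), so the rule keeps
#' the signal 4-5 times its noise: enough power for the deletion t-test at
#' the finest usable breakpoint resolution.
#'
#' @param depth per-base depth vector; must cover at least 100 bins of the
#'   largest candidate.
#' @param candidates ordered candidate bin sizes (bp).
#' @param ratio_bounds inclusive `[low, high]` bounds on mean/SD.
#' @param force_largest if no candidate qualifies, return the largest
#'   candidate instead of erroring.
#' @return the chosen bin size, with the per-candidate ratios attached as
#'   attribute `"ratios"`.  If no candidate qualifies and `force_largest`
#'   is `FALSE`, an error of class `binSizeError` is thrown whose
#'   `ratios` field carries the per-candidate ratios.
#' @export
selectBinSize <- function(depth,
                          candidates = c(70, 85, 100, 150, 200, 250),
                          ratio_bounds = c(4, 5),
                          force_largest = FALSE) {
    candidates <- sort(candidates)
    if (length(depth) < max(candidates) * 100)
        stop(sprintf("depth vector too short: need >= %d bp",
                     max(candidates) * 100))
    ratios <- vapply(candidates, function(b) {
        bins <- binDepth(depth, b)
        s <- stats::sd(bins)
        if (s == 0) return(Inf)
        mean(bins) / s
    }, 0)
    names(ratios) <- as.character(candidates)
    ok <- is.finite(ratios) & ratios >= ratio_bounds[1] &
        ratios <= ratio_bounds[2]
    if (any(ok)) {
        chosen <- candidates[which(ok)[1]]
        return(structure(chosen, ratios = ratios))
    }
    if (force_largest)
        return(structure(max(candidates), ratios = ratios, forced = TRUE))
    stop(structure(class = c("binSizeError", "error", "condition"),
                   list(message = sprintf(
                            "no candidate bin size has mean/SD in [%g, %g]; ratios: %s",
                            ratio_bounds[1], ratio_bounds[2],
                            paste(sprintf("%s=%.3g", names(ratios), ratios),
                                  collapse = ", ")),
                        call = sys.call(-1), ratios = ratios)))
}

#' Real-valued copy-number estimate of a region
#'
#' CN = 2 x mean(regional bin depths) / global mean bin depth: the factor
#' by which the region's read depth differs from its surroundings, on the
#' diploid scale.
#'
#' @param regional_bins depths of the bins inside the candidate region.
#' @param global_mean mean bin depth of the surrounding signal (> 0).
#' @return non-negative real CN estimate.
#' @export
estimateCn <- function(regional_bins, global_mean) {
    if (length(regional_bins) == 0) stop("empty region")
    if (!is.finite(global_mean) || global_mean <= 0)
        stop("global mean depth must be positive")
    2 * mean(regional_bins) / global_mean
}

#' One-sample t-test of a region's depth against the global mean
#'
#' Two-sided one-sample t-test of the regional bin depths against the
#' global mean depth.  When the regional standard deviation is zero the
#' test statistic is undefined; by convention p = 0 if the regional mean
#' differs from the global mean and p = 1 if it equals it.
#'
#' @param regional_bins depths of >= 2 bins.
#' @param global_mean global mean bin depth.
#' @return two-sided p-value in `[0, 1]`.
#' @export
callSignificance <- function(regional_bins, global_mean) {
    n <- length(regional_bins)
    if (n < 2) stop("need >= 2 regional bins")
    s <- stats::sd(regional_bins)
    m <- mean(regional_bins)
    if (s == 0) return(if (m == global_mean) 1 else 0)
    t <- (m - global_mean) / (s / sqrt(n))
    2 * stats::pt(-abs(t), df = n - 1)
}

#' Depth-weighted q0 fraction of a region
#'
#' @param q0_bins per-bin q0 fractions over the region.
#' @param depth_bins per-bin depths (weights).
#' @return weighted mean q0 in `[0, 1]`; 0 by convention when the total
#'   depth is zero.
#' @export
computeQ0 <- function(q0_bins, depth_bins) {
    if (length(q0_bins) == 0) stop("empty region")
    stopifnot(length(q0_bins) == length(depth_bins))
    tot <- sum(depth_bins)
    if (tot == 0) return(0)
    sum(q0_bins * depth_bins) / tot
}

#' Segment a binned depth profile into CNV calls
#'
#' Maximal runs of at least `min_bins` consecutive bins whose depth ratio
#' to the chromosome's global mean is below `del_ratio` (deletion) or
#' above `dup_ratio` (duplication) become candidate calls, provided the
#' run spans at least `min_width` bp.  Each call is annotated with
#' [estimateCn()], [callSignificance()] and [computeQ0()].  This run-based
#' thresholding stands in for a full mean-shift partitioning; it is
#' adequate to feed the genotyping matrix and its thresholds are exposed.
#'
#' @param bins per-bin depth sums for one chromosome (from [binDepth()]).
#' @param q0_bins per-bin q0 fractions (same length; defaults to zeros).
#' @param bin_size the bin width used.
#' @param chrom chromosome name.
#' @param sample_id sample identifier attached to the calls.
#' @param del_ratio,dup_ratio depth-ratio thresholds marking candidate
#'   deletion/duplication bins.
#' @param min_bins minimum run length in bins.
#' @param min_width minimum call width in bp (calls shorter than this are
#'   dropped; per-sample CNV reporting starts at 1 kbp).
#' @return `GRanges` of calls in the [readCnvCalls()] layout (possibly
#'   empty).  The global mean is computed over the given chromosome's
#'   bins.
#' @export
segmentDepth <- function(bins, q0_bins = NULL, bin_size, chrom = "1",
                         sample_id = "sample1", del_ratio = 0.75,
                         dup_ratio = 1.25, min_bins = 5,
                         min_width = 1000) {
    if (is.null(q0_bins)) q0_bins <- numeric(length(bins))
    global_mean <- mean(bins)
    ratio <- bins / global_mean
    state <- ifelse(ratio < del_ratio, -1L, ifelse(ratio > dup_ratio, 1L, 0L))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    recs <- list()
    for (k in seq_along(r$values)) {
        if (r$values[k] == 0L || r$lengths[k] < min_bins) next
        i0 <- starts[k]; i1 <- ends[k]
        width <- (i1 - i0 + 1) * bin_size
        if (width < min_width) next
        reg <- bins[i0:i1]
        cn <- estimateCn(reg, global_mean)
        p <- callSignificance(reg, global_mean)
        q0 <- computeQ0(q0_bins[i0:i1], reg)
        gr <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges((i0 - 1) * bin_size + 1,
                                    i1 * bin_size))
        mcols(gr)$sample_id <- sample_id
        mcols(gr)$sv_type <- if (r$values[k] < 0) "deletion" else
            "duplication"
        mcols(gr)$cn <- cn
        mcols(gr)$p_value <- p
        mcols(gr)$q0 <- q0
        recs[[length(recs) + 1]] <- gr
    }
    if (length(recs) == 0) return(.empty_calls())
    do.call(c, recs)
}

#' Call CNVs from a per-base depth profile
#'
#' Convenience wrapper running [selectBinSize()], [binDepth()] and
#' [segmentDepth()] on one chromosome's per-base depth and q0 tracks.
#'
#' @inheritParams selectBinSize
#' @inheritParams segmentDepth
#' @param q0 per-base q0 fractions (defaults to zeros).
#' @param bin_size optional fixed bin size; when `NULL` it is selected by
#'   [selectBinSize()].
#' @return `GRanges` of calls with the chosen bin size attached as
#'   attribute `"bin_size"`.
#' @export
callCnvs <- function(depth, q0 = NULL, chrom = "1", sample_id = "sample1",
                     candidates = c(70, 85, 100, 150, 200, 250),
                     bin_size = NULL, force_largest = FALSE, ...) {
    if (is.null(q0)) q0 <- numeric(length(depth))
    if (is.null(bin_size))
        bin_size <- as.numeric(selectBinSize(depth, candidates,
                                             force_largest = force_largest))
    b <- binDepth(depth, bin_size, q0 = q0)
    calls <- segmentDepth(b$depth, b$q0, bin_size = bin_size, chrom = chrom,
                          sample_id = sample_id, ...)
    attr(calls, "bin_size") <- bin_size
    calls
}
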