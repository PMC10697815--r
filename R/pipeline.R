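## End-to-end cohort pipeline on synthetic data.
##
## Chains the generator, the two-tier QC + CN matrix construction, protein
## normalization, the association scan and clumping, and evaluates
## recovery of the planted CNV-protein effects.

#' Run the full pipeline on one synthetic cohort
#'
#' @param config a [simConfig()]; `config$seed` drives every stage.
#' @return list with `genotypes`, `calls`, `matrix` (the
#'   [buildCnMatrix()] output), `proteins`, `normalized`, `scan` (the
#'   [associationScan()] output), `significant` (the sub-threshold
#'   results), `clumps` (per-window assignments) and `clump_summary`.
#' @export
runCohortPipeline <- function(config) {
    g <- simulateGenotypes(config)
    calls <- simulateCnvCalls(g, config)
    mats <- buildCnMatrix(calls, config$chromosome_lengths,
                          rownames(g$cn))
    prot <- simulateProteins(g, config)
    norm <- normalizeProteins(prot$proteins, prot$covariates)
    scan <- associationScan(mats$merged, norm, prot$pcs,
                            n_pcs = config$n_pcs)
    res <- scan$results
    sig <- res[!is.na(res$p_value) & res$p_value < scan$plan$threshold, ,
               drop = FALSE]
    clumps <- NULL; clump_summary <- NULL
    if (nrow(sig) > 0) {
        wins <- rowRanges(mats$merged)[sig$cnv_idx]
        cnrows <- cnValues(mats$merged)[sig$cnv_idx, , drop = FALSE]
        clumps <- clumpWindows(wins, sig$p_value, cnrows,
                               protein_id = sig$protein_id)
        clump_summary <- summarizeClumps(clumps, wins, sig$p_value)
    }
    list(genotypes = g, calls = calls, matrix = mats, proteins = prot,
         normalized = norm, scan = scan, significant = sig,
         clumps = clumps, clump_summary = clump_summary)
}

#' Evaluate recovery of the planted effects
#'
#' A planted (region, protein) effect counts as recovered when a clump for
#' that protein has a span within `slack` bp of the truth interval;
#' clumps matching no planted effect under the same rule are false
#' positives.  The slack absorbs breakpoint jitter, which lets recovered
#' signals extend slightly beyond the planted interval.
#'
#' @param pipe output of [runCohortPipeline()].
#' @param config the [simConfig()] used.
#' @param slack matching slack in bp.
#' @return list with `n_planted`, `n_recovered`, `recovered` (logical per
#'   planted effect), `n_clumps`, `n_false_positives`.
#' @export
evaluateRecovery <- function(pipe, config, slack = 2000) {
    eff <- config$effects
    reg <- config$regions
    cs <- pipe$clump_summary
    n_planted <- nrow(eff)
    if (is.null(cs) || nrow(cs) == 0)
        return(list(n_planted = n_planted, n_recovered = 0L,
                    recovered = rep(FALSE, n_planted), n_clumps = 0L,
                    n_false_positives = 0L))
    matches_effect <- function(k) {
        r <- reg[reg$region_id == eff$region_id[k], ]
        cs$protein_id == eff$protein_id[k] &
            cs$chrom == r$chrom &
            cs$span_start <= r$end + slack &
            cs$span_end >= r$start - slack
    }
    match_mat <- vapply(seq_len(n_planted), matches_effect,
                        logical(nrow(cs)))
    match_mat <- matrix(match_mat, nrow = nrow(cs))
    recovered <- apply(match_mat, 2, any)
    fp <- sum(!apply(match_mat, 1, any))
    list(n_planted = n_planted, n_recovered = sum(recovered),
         recovered = recovered, n_clumps = nrow(cs),
         n_false_positives = fp)
}

#' Seed sweep of planted-effect recovery
#'
#' Runs [runCohortPipeline()] + [evaluateRecovery()] over `n_seeds`
#' consecutive seeds and reports the fraction of seeds in which every
#' planted effect is recovered with at most `fp_max` false-positive
#' clumps.
#'
#' @param config base [simConfig()]; its seed field is replaced per run.
#' @param n_seeds number of seeds.
#' @param base_seed first seed.
#' @param fp_max allowed false positives per seed.
#' @return list with `success_rate`, and per-seed vectors `recovered_all`,
#'   `false_positives`.
#' @export
recoverySweep <- function(config, n_seeds = 20, base_seed = 1,
                          fp_max = 1) {
    rec <- logical(n_seeds)
    fps <- integer(n_seeds)
    for (k in seq_len(n_seeds)) {
        cfg <- config
        cfg$seed <- as.integer(base_seed + k - 1)
        pipe <- runCohortPipeline(cfg)
        ev <- evaluateRecovery(pipe, cfg)
        rec[k] <- ev$n_recovered == ev$n_planted
        fps[k] <- ev$n_false_positives
    }
    list(success_rate = mean(rec & fps <= fp_max),
         recovered_all = rec, false_positives = fps)
}

#' Null-cohort association p-values
#'
#' Runs the pipeline on cohorts with every planted effect removed and
#' accumulates the association p-values across seeds until at least
#' `n_needed` tests are collected; used for calibration checks (KS
#' uniformity, genomic inflation under the null).
#'
#' @param config base [simConfig()] (its effects are dropped).
#' @param n_needed number of p-values to collect.
#' @param base_seed first seed.
#' @return numeric vector of at least `n_needed` p-values (or fewer if 25
#'   seeds do not suffice).
#' @export
nullPvalues <- function(config, n_needed = 1e4, base_seed = 1) {
    cfg <- config
    cfg$effects <- cfg$effects[0, , drop = FALSE]
    out <- numeric(0)
    k <- 0L
    while (length(out) < n_needed && k < 25L) {
        k <- k + 1L
        cfg$seed <- as.integer(base_seed + k - 1)
        pipe <- runCohortPipeline(cfg)
        out <- c(out, pipe$scan$results$p_value)
    }
    out
}

#' Configuration of the long-read validation scenario
#'
#' A 12-sample validation subcohort genotyped over many rare CNVs, each
#' carried by exactly one individual, so the per-CNV validation outcome
#' reflects the long-read caller's per-event recall directly.  Regions
#' are window-aligned, jitter-free deletions and duplications; call noise
#' and QC-failure channels are off so the comparison isolates the
#' long-read sensitivity asymmetry (deletions recovered well,
#' duplications poorly).
#'
#' @param n_del,n_dup numbers of deletion and duplication regions.
#' @param n_samples subcohort size.
#' @param sensitivity per-event long-read recall by SV type.
#' @param seed RNG seed.
#' @return a [simConfig()].
#' @export
validationConfig <- function(n_del = 150, n_dup = 150, n_samples = 12,
                             sensitivity = c(DEL = 0.95, DUP = 0.05),
                             seed = 1) {
    n <- n_del + n_dup
    start <- 10001 + (seq_len(n) - 1) * 15000
    regions <- data.frame(
        region_id = sprintf("vreg%03d", seq_len(n)),
        chrom = "1",
        start = start,
        end = start + 2000 - 1,
        sv_type = rep(c("deletion", "duplication"), c(n_del, n_dup)),
        allele_frequency = 0.1,
        cn_per_allele = rep(c(-1, 1), c(n_del, n_dup)),
        breakpoint_jitter_sd = 0,
        stringsAsFactors = FALSE)
    simConfig(n_samples = n_samples,
              chromosome_lengths = c(`1` = max(regions$end) + 10000),
              regions = regions,
              effects = defaultEffects()[0, , drop = FALSE],
              n_proteins = 2,
              call_q0_fail_rate = 0, noise_call_rate = 0,
              longread_sensitivity = sensitivity,
              low_yield_rate = 0, low_coverage_rate = 0,
              seed = seed)
}

#' Run the short-read vs long-read validation pipeline
#'
#' Generates singleton-carrier genotypes, runs the call + CN-matrix
#' stages, simulates the long-read call set, classifies per-(CNV, sample)
#' concordance and summarizes per-CNV validation, reporting the fraction
#' of represented deletion and duplication CNVs validated to 100%.
#'
#' @param config a [validationConfig()].
#' @param mode overlap mode passed to [classifyConcordance()].
#' @return list with `summary` (per-CNV table joined with the truth
#'   region's SV type), `records`, `del_validated_frac`,
#'   `dup_validated_frac` (fractions over CNVs with >= 1 carrier among
#'   samples passing yield QC).
#' @export
runValidationPipeline <- function(config, mode = "reciprocal_50") {
    g <- singletonGenotypes(config)
    calls <- simulateCnvCalls(g, config)
    mats <- buildCnMatrix(calls, config$chromosome_lengths,
                          rownames(g$cn))
    lr <- simulateLongreadCalls(g, config)
    merged <- mats$merged
    ## align the regional-coverage rows with the merged CNVs
    reg_gr <- GenomicRanges::GRanges(
        config$regions$chrom,
        IRanges::IRanges(config$regions$start, config$regions$end))
    hit <- GenomicRanges::findOverlaps(rowRanges(merged), reg_gr,
                                       select = "first")
    stopifnot(!anyNA(hit))
    coverage <- lr$coverage[hit, , drop = FALSE]
    records <- classifyConcordance(merged, lr$records, lr$yields,
                                   coverage, mode = mode)
    summary <- summarizeValidation(records)
    summary$sv_type <- config$regions$sv_type[hit[summary$cnv_idx]]
    del <- summary$sv_type == "deletion" & summary$n_del_carriers >= 1
    dup <- summary$sv_type == "duplication" & summary$n_dup_carriers >= 1
    list(summary = summary, records = records,
         del_validated_frac = if (any(del))
             mean(summary$validated_100[del]) else NA_real_,
         dup_validated_frac = if (any(dup))
             mean(summary$validated_100[dup]) else NA_real_)
}
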