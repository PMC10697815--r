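## Synthetic cohorts with planted truth.
##
## The generator emulates the features of a population WGS + plasma-proteome
## study that the pipeline's statistics depend on: polymorphic CNV regions
## segregating under Hardy-Weinberg with real-valued CN estimates,
## per-sample breakpoint jitter, protein traits with planted linear CN
## effects plus age/sex/batch and principal-component structure, SNPs in
## controlled LD with the CNVs, and long-read SV call sets whose
## sensitivity differs by SV type (deletions recovered well, duplications
## poorly).  Every generator is a deterministic function of (config, seed).

#' Default truth regions for the synthetic cohort
#'
#' Thirty polymorphic CNV regions spread over two 5-Mbp chromosomes,
#' alternating deletions and duplications, with allele frequencies cycling
#' through 0.05-0.4 and breakpoint jitter standard deviations of 0, 100 and
#' 200 bp (sample-level jitter, as seen in population read-depth traces).
#'
#' @param n_regions number of regions.
#' @return data.frame with columns `region_id`, `chrom`, `start`, `end`,
#'   `sv_type`, `allele_frequency`, `cn_per_allele`,
#'   `breakpoint_jitter_sd`.
#' @export
defaultTruthRegions <- function(n_regions = 30) {
    i <- seq_len(n_regions)
    widths <- c(1200, 2000, 3000, 4200, 5000)[(i - 1) %% 5 + 1]
    chrom <- ifelse(i <= ceiling(n_regions / 2), "1", "2")
    within_idx <- ifelse(i <= ceiling(n_regions / 2), i,
                         i - ceiling(n_regions / 2))
    start <- 200001 + (within_idx - 1) * 150000
    sv_type <- ifelse(i %% 2 == 1, "deletion", "duplication")
    data.frame(
        region_id = sprintf("region%02d", i),
        chrom = chrom,
        start = start,
        end = start + widths - 1,
        sv_type = sv_type,
        allele_frequency = c(0.05, 0.1, 0.2, 0.3, 0.4)[(i - 1) %% 5 + 1],
        cn_per_allele = ifelse(sv_type == "deletion", -1, 1),
        breakpoint_jitter_sd = c(0, 100, 200)[(i - 1) %% 3 + 1],
        stringsAsFactors = FALSE)
}

#' Default planted CNV-protein effects
#'
#' Two planted effects with |beta| >= 0.6 on regions with allele frequency
#' >= 0.1, the configuration used by the end-to-end recovery checks.
#'
#' @return data.frame with columns `region_id`, `protein_id`, `beta`.
#' @export
defaultEffects <- function() {
    data.frame(region_id = c("region05", "region18"),
               protein_id = c("prot03", "prot11"),
               beta = c(0.8, -0.7),
               stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' @param n_samples cohort size.
#' @param chromosome_lengths named numeric vector of chromosome lengths
#'   (bp).
#' @param regions truth-region table as from [defaultTruthRegions()].
#' @param effects planted-effect table as from [defaultEffects()]; use a
#'   zero-row table for a null cohort.
#' @param n_proteins,n_pcs numbers of simulated proteins and genetic
#'   principal components.
#' @param pc_effect_sd standard deviation of per-protein PC loadings.
#' @param noise_sd residual standard deviation of the protein model.
#' @param mean_depth mean sequencing depth (reads per bp) for read-depth
#'   simulation.
#' @param missing_rate protein missingness rate.
#' @param call_cn_sd measurement noise added to the true CN of a call.
#' @param call_q0_fail_rate fraction of carrier calls assigned q0 >= 0.5
#'   (failing alignment-quality QC).
#' @param noise_call_rate expected number of spurious low-significance
#'   calls per sample.
#' @param longread_sensitivity named vector, per-carrier-event recall
#'   probabilities for `DEL` and `DUP` long-read calls.
#' @param dup_as_insertions emit duplication carriers as clusters of small
#'   insertions rather than one DUP record (the behaviour long-read callers
#'   show at tandem-repeat expansions).
#' @param low_yield_rate fraction of samples assigned sequencing yield
#'   below 30 Gbp (failing long-read coverage QC).
#' @param low_coverage_rate fraction of (region, sample) cells assigned
#'   regional long-read coverage below the assessability threshold.
#' @param snp_ld_targets named numeric vector mapping `region_id` to a
#'   target squared Spearman correlation for a tag SNP.
#' @param n_null_snps unlinked SNPs added to the SNP set.
#' @param seed integer seed; mandatory, all generators derive their RNG
#'   streams from it.
#'
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(n_samples = 500,
                      chromosome_lengths = c(`1` = 5e6, `2` = 5e6),
                      regions = defaultTruthRegions(),
                      effects = defaultEffects(),
                      n_proteins = 20,
                      n_pcs = 4,
                      pc_effect_sd = 0.2,
                      noise_sd = 1,
                      mean_depth = 30,
                      missing_rate = 0.02,
                      call_cn_sd = 0.05,
                      call_q0_fail_rate = 0.03,
                      noise_call_rate = 0.2,
                      longread_sensitivity = c(DEL = 0.9, DUP = 0.1),
                      dup_as_insertions = FALSE,
                      low_yield_rate = 0.1,
                      low_coverage_rate = 0.05,
                      snp_ld_targets = NULL,
                      n_null_snps = 5,
                      seed = 1) {
    if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
    stopifnot(n_samples >= 1,
              all(chromosome_lengths > 0),
              all(regions$allele_frequency >= 0),  # 0 = degenerate, testing
              all(regions$allele_frequency < 1),
              all(regions$end > regions$start),
              all(regions$breakpoint_jitter_sd <
                      (regions$end - regions$start + 1) / 2),
              all(regions$chrom %in% names(chromosome_lengths)),
              all(longread_sensitivity >= 0 & longread_sensitivity <= 1),
              missing_rate >= 0 && missing_rate < 1,
              is.null(snp_ld_targets) ||
                  all(snp_ld_targets >= 0 & snp_ld_targets <= 1))
    if (nrow(effects) > 0) {
        stopifnot(all(effects$region_id %in% regions$region_id),
                  all(is.finite(effects$beta)))
    }
    structure(list(
        n_samples = n_samples, chromosome_lengths = chromosome_lengths,
        regions = regions, effects = effects, n_proteins = n_proteins,
        n_pcs = n_pcs, pc_effect_sd = pc_effect_sd, noise_sd = noise_sd,
        mean_depth = mean_depth, missing_rate = missing_rate,
        call_cn_sd = call_cn_sd, call_q0_fail_rate = call_q0_fail_rate,
        noise_call_rate = noise_call_rate,
        longread_sensitivity = longread_sensitivity,
        dup_as_insertions = dup_as_insertions,
        low_yield_rate = low_yield_rate,
        low_coverage_rate = low_coverage_rate,
        snp_ld_targets = snp_ld_targets, n_null_snps = n_null_snps,
        seed = as.integer(seed)), class = "SimConfig")
}

.sample_ids <- function(config) sprintf("s%04d", seq_len(config$n_samples))

#' Simulate diploid CNV genotypes under Hardy-Weinberg equilibrium
#'
#' For each truth region, two allele indicators per sample are drawn as
#' Bernoulli(allele frequency); CN = 2 + dosage x cn_per_allele.  Realized
#' breakpoints are the truth interval shifted by rounded Normal(0,
#' jitter_sd) offsets, shared by the two alleles of one sample
#' (breakpoint variation is a sample-level feature of read-depth data;
#' phase is unobservable).
#'
#' @param config a [simConfig()].
#' @return list with matrices (samples x regions) `cn`, `dosage`,
#'   `start`, `end`, the per-region allele indicator matrices `a1`, `a2`,
#'   and the `regions` table.
#' @export
simulateGenotypes <- function(config) {
    set.seed(config$seed)
    n <- config$n_samples
    reg <- config$regions
    R <- nrow(reg)
    ids <- .sample_ids(config)
    a1 <- matrix(0L, n, R); a2 <- matrix(0L, n, R)
    cn <- matrix(2, n, R)
    st <- matrix(0L, n, R); en <- matrix(0L, n, R)
    for (r in seq_len(R)) {
        q <- reg$allele_frequency[r]
        a1[, r] <- stats::rbinom(n, 1, q)
        a2[, r] <- stats::rbinom(n, 1, q)
        d <- a1[, r] + a2[, r]
        cn[, r] <- pmax(0, 2 + d * reg$cn_per_allele[r])
        js <- reg$breakpoint_jitter_sd[r]
        off_s <- if (js > 0) round(stats::rnorm(n, 0, js)) else rep(0, n)
        off_e <- if (js > 0) round(stats::rnorm(n, 0, js)) else rep(0, n)
        L <- config$chromosome_lengths[[reg$chrom[r]]]
        st[, r] <- pmin(pmax(reg$start[r] + off_s, 1), L - 1)
        en[, r] <- pmin(pmax(reg$end[r] + off_e, st[, r] + 1), L)
    }
    dimnames(cn) <- dimnames(a1) <- dimnames(a2) <-
        dimnames(st) <- dimnames(en) <- list(ids, reg$region_id)
    list(cn = cn, dosage = a1 + a2, start = st, end = en,
         a1 = a1, a2 = a2, regions = reg)
}

#' Assign exactly one heterozygous carrier per region
#'
#' A variant of [simulateGenotypes()] for validation-subcohort scenarios in
#' which each CNV is rare enough to be carried by a single individual, so
#' per-region validation reflects the per-event long-read recall directly.
#'
#' @param config a [simConfig()] (typically with a small `n_samples`).
#' @return same structure as [simulateGenotypes()].
#' @export
singletonGenotypes <- function(config) {
    g <- simulateGenotypes(config)
    set.seed(config$seed + 11L)
    n <- config$n_samples
    R <- nrow(config$regions)
    g$a1[] <- 0L; g$a2[] <- 0L
    carrier <- sample.int(n, R, replace = TRUE)
    for (r in seq_len(R)) g$a1[carrier[r], r] <- 1L
    g$dosage <- g$a1 + g$a2
    g$cn <- 2 + sweep(g$dosage, 2, config$regions$cn_per_allele, `*`)
    g$cn <- pmax(g$cn, 0)
    dimnames(g$cn) <- dimnames(g$dosage) <- dimnames(g$a1)
    g
}

#' Simulate per-sample CNV call tables from true genotypes
#'
#' Each carrier produces one call on the sample's realized interval, with
#' CN = true CN plus Normal measurement noise (kept on the correct side of
#' 2), a highly significant t-test p-value, and a low q0 except for a
#' configured fraction that fails the alignment-quality filter.  Spurious
#' low-significance calls are added at a configurable per-sample rate to
#' exercise the two-tier QC.
#'
#' @param genotypes output of [simulateGenotypes()].
#' @param config a [simConfig()].
#' @return `GRanges` of calls with metadata columns `sample_id`, `sv_type`,
#'   `cn`, `p_value`, `q0` (the [readCnvCalls()] layout).
#' @export
simulateCnvCalls <- function(genotypes, config) {
    set.seed(config$seed + 1L)
    reg <- genotypes$regions
    ids <- rownames(genotypes$cn)
    acc <- list(chrom = character(0), start = numeric(0), end = numeric(0),
                sample_id = character(0), sv_type = character(0),
                cn = numeric(0), p_value = numeric(0), q0 = numeric(0))
    add <- function(acc, chrom, start, end, sample_id, sv_type, cn, p, q0) {
        list(chrom = c(acc$chrom, chrom), start = c(acc$start, start),
             end = c(acc$end, end),
             sample_id = c(acc$sample_id, sample_id),
             sv_type = c(acc$sv_type, sv_type), cn = c(acc$cn, cn),
             p_value = c(acc$p_value, p), q0 = c(acc$q0, q0))
    }
    for (r in seq_len(nrow(reg))) {
        carriers <- which(genotypes$dosage[, r] > 0)
        if (length(carriers) == 0) next
        k <- length(carriers)
        true_cn <- genotypes$cn[carriers, r]
        cn <- true_cn + stats::rnorm(k, 0, config$call_cn_sd)
        if (reg$sv_type[r] == "deletion") {
            cn <- pmin(pmax(cn, 0), 1.99)
        } else cn <- pmax(cn, 2.01)
        q0 <- stats::runif(k, 0, 0.25)
        fail <- stats::runif(k) < config$call_q0_fail_rate
        q0[fail] <- stats::runif(sum(fail), 0.5, 0.9)
        acc <- add(acc, rep(reg$chrom[r], k), genotypes$start[carriers, r],
                   genotypes$end[carriers, r], ids[carriers],
                   rep(reg$sv_type[r], k), cn,
                   10^(-stats::runif(k, 8, 25)), q0)
    }
    ## spurious calls: plausible CN, weak significance
    n_noise <- stats::rpois(length(ids), config$noise_call_rate)
    for (i in which(n_noise > 0)) {
        for (j in seq_len(n_noise[i])) {
            chrom <- sample(names(config$chromosome_lengths), 1)
            L <- config$chromosome_lengths[[chrom]]
            w <- sample(c(1000, 1600, 2400), 1)
            s <- sample.int(L - w, 1)
            del <- stats::runif(1) < 0.5
            acc <- add(acc, chrom, s, s + w - 1, ids[i],
                       if (del) "deletion" else "duplication",
                       if (del) stats::runif(1, 1.3, 1.6)
                       else stats::runif(1, 2.4, 2.7),
                       10^(-stats::runif(1, 1, 4.5)),
                       stats::runif(1, 0, 0.25))
        }
    }
    if (length(acc$chrom) == 0) return(.empty_calls())
    gr <- GenomicRanges::GRanges(acc$chrom,
                                 IRanges::IRanges(acc$start, acc$end))
    mcols(gr)$sample_id <- acc$sample_id
    mcols(gr)$sv_type <- acc$sv_type
    mcols(gr)$cn <- acc$cn
    mcols(gr)$p_value <- acc$p_value
    mcols(gr)$q0 <- acc$q0
    gr
}

#' Simulate a per-base read-depth profile for one chromosome of one sample
#'
#' Expected depth is `mean_depth * CN / 2` inside each copy-number
#' interval and `mean_depth` elsewhere; observed depth is Poisson.  The
#' per-base q0 track is zero except in designated ambiguous-alignment
#' regions.
#'
#' @param cn_intervals `GRanges` with a numeric `cn` metadata column (may
#'   be empty for a diploid profile).
#' @param length chromosome length (bp).
#' @param mean_depth expected diploid depth (reads per bp).
#' @param seed RNG seed.
#' @param q0_intervals optional `GRanges` where ambiguous-alignment mass is
#'   injected.
#' @param q0_value the q0 fraction inside `q0_intervals`.
#' @return list with integer vector `depth` and numeric vector `q0`, both
#'   of length `length`.
#' @export
simulateReadDepth <- function(cn_intervals, length, mean_depth = 30,
                              seed = 1, q0_intervals = NULL,
                              q0_value = 0.7) {
    set.seed(seed)
    lambda <- rep(mean_depth, length)
    if (!is.null(cn_intervals) && base::length(cn_intervals) > 0) {
        for (i in seq_along(cn_intervals)) {
            s <- GenomicRanges::start(cn_intervals)[i]
            e <- min(GenomicRanges::end(cn_intervals)[i], length)
            lambda[s:e] <- mean_depth * mcols(cn_intervals)$cn[i] / 2
        }
    }
    depth <- stats::rpois(length, lambda)
    q0 <- numeric(length)
    if (!is.null(q0_intervals) && base::length(q0_intervals) > 0) {
        for (i in seq_along(q0_intervals)) {
            s <- GenomicRanges::start(q0_intervals)[i]
            e <- min(GenomicRanges::end(q0_intervals)[i], length)
            q0[s:e] <- q0_value
        }
    }
    list(depth = depth, q0 = q0)
}

#' Simulate protein measurements, covariates and principal components
#'
#' Each protein is a linear combination of the planted CN effects, small
#' loadings on the genetic principal components, age, sex and batch
#' effects, plus Normal residual noise; a configurable fraction of
#' measurements is set missing.
#'
#' @param genotypes output of [simulateGenotypes()].
#' @param config a [simConfig()].
#' @return list with `proteins` (samples x proteins matrix), `covariates`
#'   (data.frame `sample_id`, `age`, `sex`, `batch`), and `pcs`
#'   (samples x n_pcs matrix).
#' @export
simulateProteins <- function(genotypes, config) {
    set.seed(config$seed + 2L)
    n <- config$n_samples
    ids <- rownames(genotypes$cn)
    prot_ids <- sprintf("prot%02d", seq_len(config$n_proteins))
    age <- round(stats::runif(n, 30, 75))
    sex <- stats::rbinom(n, 1, 0.5)
    batch <- sample(paste0("b", 1:4), n, replace = TRUE)
    pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs,
                  dimnames = list(ids, paste0("PC", seq_len(config$n_pcs))))
    batch_levels <- sort(unique(batch))
    prot <- matrix(0, n, config$n_proteins, dimnames = list(ids, prot_ids))
    for (j in seq_len(config$n_proteins)) {
        loadings <- stats::rnorm(config$n_pcs, 0, config$pc_effect_sd)
        beff <- stats::rnorm(length(batch_levels), 0, 0.3)
        names(beff) <- batch_levels
        y <- drop(pcs %*% loadings) + 0.01 * age + 0.3 * sex +
            beff[batch] + stats::rnorm(n, 0, config$noise_sd)
        eff <- config$effects[config$effects$protein_id == prot_ids[j], ,
                              drop = FALSE]
        if (nrow(eff) > 0) {
            for (k in seq_len(nrow(eff)))
                y <- y + eff$beta[k] * genotypes$cn[, eff$region_id[k]]
        }
        prot[, j] <- y
    }
    if (config$missing_rate > 0) {
        miss <- matrix(stats::runif(n * config$n_proteins) <
                           config$missing_rate, n)
        prot[miss] <- NA
    }
    list(proteins = prot,
         covariates = data.frame(sample_id = ids, age = age, sex = sex,
                                 batch = batch, stringsAsFactors = FALSE),
         pcs = pcs)
}

#' Simulate SNPs in controlled LD with the CNV regions
#'
#' For each region with a target R-squared, a tag SNP is built by copying
#' each CNV allele indicator with probability `sqrt(target)` and drawing a
#' fresh Bernoulli(allele frequency) otherwise; the allele-level
#' correlation is then `sqrt(target)` in expectation, so the realized
#' squared Spearman correlation lands within about 0.1 of the target at
#' n >= 500.  Unlinked SNPs with random frequencies are appended.
#'
#' @param genotypes output of [simulateGenotypes()].
#' @param config a [simConfig()] with non-`NULL` `snp_ld_targets`.
#' @return list with `dosage` (samples x SNPs 0/1/2 matrix) and
#'   `positions` (`GRanges`), tag SNPs named `tag_<region_id>`.
#' @export
simulateSnps <- function(genotypes, config) {
    set.seed(config$seed + 3L)
    n <- config$n_samples
    ids <- rownames(genotypes$cn)
    targets <- config$snp_ld_targets
    cols <- list(); pos <- list()
    reg <- genotypes$regions
    for (rid in names(targets)) {
        r <- match(rid, reg$region_id)
        stopifnot(!is.na(r))
        s <- sqrt(targets[[rid]])
        q <- reg$allele_frequency[r]
        copy1 <- stats::runif(n) < s
        copy2 <- stats::runif(n) < s
        b1 <- ifelse(copy1, genotypes$a1[, r], stats::rbinom(n, 1, q))
        b2 <- ifelse(copy2, genotypes$a2[, r], stats::rbinom(n, 1, q))
        cols[[paste0("tag_", rid)]] <- b1 + b2
        pos[[paste0("tag_", rid)]] <- GenomicRanges::GRanges(
            reg$chrom[r],
            IRanges::IRanges(max(1, reg$start[r] - 5000), width = 1))
    }
    for (k in seq_len(config$n_null_snps)) {
        q <- stats::runif(1, 0.1, 0.5)
        chrom <- sample(names(config$chromosome_lengths), 1)
        cols[[sprintf("null_snp%02d", k)]] <- stats::rbinom(n, 2, q)
        pos[[sprintf("null_snp%02d", k)]] <- GenomicRanges::GRanges(
            chrom,
            IRanges::IRanges(
                sample.int(config$chromosome_lengths[[chrom]], 1),
                width = 1))
    }
    dosage <- do.call(cbind, cols)
    rownames(dosage) <- ids
    positions <- suppressWarnings(do.call(c, unname(pos)))
    names(positions) <- names(cols)
    list(dosage = dosage, positions = positions)
}

#' Simulate long-read SV call sets with SV-type-dependent sensitivity
#'
#' Each true carrier event is emitted with probability
#' `longread_sensitivity[sv_type]` as a DEL or DUP record with jittered
#' breakpoints (optionally, duplications as clusters of small insertions).
#' Per-sample molecular yields (Gbp) and a per-(region, sample) regional
#' coverage matrix are generated, with configured fractions below the
#' 30-Gbp yield and regional-coverage QC thresholds.
#'
#' @param genotypes output of [simulateGenotypes()] or
#'   [singletonGenotypes()].
#' @param config a [simConfig()].
#' @return list with `records` (`GRanges`, [readSvVcf()] layout), `yields`
#'   (named numeric, Gbp per sample) and `coverage` (regions x samples
#'   matrix of regional long-read coverage).
#' @export
simulateLongreadCalls <- function(genotypes, config) {
    set.seed(config$seed + 4L)
    reg <- genotypes$regions
    ids <- rownames(genotypes$cn)
    n <- length(ids)
    sens <- config$longread_sensitivity
    acc <- list(chrom = character(0), start = numeric(0), end = numeric(0),
                sample_id = character(0), sv_type = character(0),
                genotype = character(0))
    for (r in seq_len(nrow(reg))) {
        type <- if (reg$sv_type[r] == "deletion") "DEL" else "DUP"
        carriers <- which(genotypes$dosage[, r] > 0)
        for (i in carriers) {
            if (stats::runif(1) >= sens[[type]]) next
            s <- genotypes$start[i, r] + round(stats::rnorm(1, 0, 50))
            e <- genotypes$end[i, r] + round(stats::rnorm(1, 0, 50))
            s <- max(1, s); e <- max(s + 1, e)
            gt <- if (genotypes$dosage[i, r] == 2) "hom_alt" else "het"
            if (type == "DUP" && config$dup_as_insertions) {
                k <- 1 + stats::rpois(1, 2)
                at <- sort(sample(seq(s, e), k))
                acc$chrom <- c(acc$chrom, rep(reg$chrom[r], k))
                acc$start <- c(acc$start, at)
                acc$end <- c(acc$end, at)
                acc$sample_id <- c(acc$sample_id, rep(ids[i], k))
                acc$sv_type <- c(acc$sv_type, rep("INS", k))
                acc$genotype <- c(acc$genotype, rep(gt, k))
            } else {
                acc$chrom <- c(acc$chrom, reg$chrom[r])
                acc$start <- c(acc$start, s)
                acc$end <- c(acc$end, e)
                acc$sample_id <- c(acc$sample_id, ids[i])
                acc$sv_type <- c(acc$sv_type, type)
                acc$genotype <- c(acc$genotype, gt)
            }
        }
    }
    records <- if (length(acc$chrom) > 0) {
        gr <- GenomicRanges::GRanges(acc$chrom,
                                     IRanges::IRanges(acc$start, acc$end))
        mcols(gr)$sample_id <- acc$sample_id
        mcols(gr)$sv_type <- acc$sv_type
        mcols(gr)$genotype <- acc$genotype
        mcols(gr)$caller <- "synthetic"
        gr
    } else {
        gr <- GenomicRanges::GRanges()
        mcols(gr)$sample_id <- character(0)
        mcols(gr)$sv_type <- character(0)
        mcols(gr)$genotype <- character(0)
        mcols(gr)$caller <- character(0)
        gr
    }
    yields <- stats::rnorm(n, 45, 8)
    low <- stats::runif(n) < config$low_yield_rate
    yields[low] <- stats::runif(sum(low), 10, 29.9)
    yields <- pmax(yields, 1)
    names(yields) <- ids
    coverage <- matrix(pmax(stats::rnorm(nrow(reg) * n, 20, 4), 6),
                       nrow(reg), n,
                       dimnames = list(reg$region_id, ids))
    lowc <- matrix(stats::runif(nrow(reg) * n) <
                       config$low_coverage_rate, nrow(reg))
    coverage[lowc] <- stats::runif(sum(lowc), 0, 4)
    list(records = records, yields = yields, coverage = coverage)
}

#' Write a simulated cohort to disk in the pipeline's external formats
#'
#' Emits the CNV call TSV, protein/covariate/PC TSVs, the SNP VCF and one
#' SV VCF per sample, exercising every writer against its reader.
#'
#' @param calls `GRanges` of CNV calls.
#' @param proteins output of [simulateProteins()].
#' @param snps optional output of [simulateSnps()].
#' @param longread optional output of [simulateLongreadCalls()].
#' @param dir output directory (created if needed).
#' @return named list of the paths written, invisibly.
#' @export
writeCohort <- function(calls, proteins, snps = NULL, longread = NULL,
                        dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(calls = file.path(dir, "calls.tsv"),
                  proteins = file.path(dir, "proteins.tsv"),
                  covariates = file.path(dir, "covariates.tsv"),
                  pcs = file.path(dir, "pcs.tsv"))
    writeCnvCalls(calls, paths$calls)
    writeTsvMatrix(proteins$proteins, paths$proteins)
    utils::write.table(proteins$covariates, paths$covariates, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeTsvMatrix(proteins$pcs, paths$pcs)
    if (!is.null(snps)) {
        paths$snps <- file.path(dir, "snps.vcf")
        writeSnpVcf(snps$dosage, snps$positions, paths$snps)
    }
    if (!is.null(longread)) {
        svdir <- file.path(dir, "sv")
        dir.create(svdir, showWarnings = FALSE)
        paths$sv_dir <- svdir
        for (s in unique(mcols(longread$records)$sample_id)) {
            sel <- longread$records[
                mcols(longread$records)$sample_id == s]
            writeSvVcf(sel, file.path(svdir, paste0(s, ".vcf")),
                       sample_id = s)
        }
        paths$yields <- file.path(dir, "yields.tsv")
        utils::write.table(
            data.frame(sample_id = names(longread$yields),
                       yield_gbp = longread$yields),
            paths$yields, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(paths)
}
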