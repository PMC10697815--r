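test_that("strict-tier QC applies the per-sample Bonferroni and q0 rules", {
    df <- data.frame(
        sample_id = rep("s1", 10), sv_type = "deletion", chrom = "1",
        start = seq(1001, by = 5000, length.out = 10),
        end = seq(2000, by = 5000, length.out = 10),
        cn = 1, p_value = 1e-8, q0 = 0.2, stringsAsFactors = FALSE)
    ## n_samples = 100, 10 calls in the sample: threshold 5e-5
    df$p_value[1] <- 4e-5    # just below: retained
    df$p_value[2] <- 6e-5    # just above: removed
    df$q0[3] <- 0.5          # boundary q0: removed regardless of p
    calls <- makeCalls(df)
    kept <- qcHighConfidence(calls, n_samples = 100)
    expect_true(1001 %in% GenomicRanges::start(kept))
    expect_false(df$start[2] %in% GenomicRanges::start(kept))
    expect_false(df$start[3] %in% GenomicRanges::start(kept))
    expect_length(kept, 8)
    ## empty input is vacuously retained
    expect_length(qcHighConfidence(calls[0], 100), 0)
})

test_that("window grid tiles chromosomes with a truncated terminal window", {
    g1 <- buildWindowGrid(c(`1` = 1000))
    expect_length(g1, 5)
    expect_true(all(GenomicRanges::width(g1) == 200))

    g2 <- buildWindowGrid(c(`1` = 1050))
    expect_length(g2, 6)
    expect_equal(GenomicRanges::width(g2)[6], 50)

    g3 <- buildWindowGrid(c(`2` = 400, `1` = 600))
    expect_identical(as.character(GenomeInfoDb::seqnames(g3)),
                     c("1", "1", "1", "2", "2"))
    expect_equal(GenomicRanges::start(g3), c(1, 201, 401, 1, 201))
})

test_that("window selection uses >= 1 bp overlap with half-open boundaries", {
    grid <- buildWindowGrid(c(`1` = 1000))
    ## a call over windows 3-5 (1-based 401..900)
    call <- makeCalls(data.frame(sample_id = "s1", sv_type = "deletion",
                                 chrom = "1", start = 401, end = 900,
                                 cn = 1, p_value = 1e-9, q0 = 0))
    sel <- selectWindows(call, grid)
    expect_equal(GenomicRanges::start(sel), c(401, 601, 801))
    ## a call ending exactly at a window boundary does not leak over
    call2 <- makeCalls(data.frame(sample_id = "s1", sv_type = "deletion",
                                  chrom = "1", start = 201, end = 400,
                                  cn = 1, p_value = 1e-9, q0 = 0))
    sel2 <- selectWindows(call2, grid)
    expect_equal(GenomicRanges::start(sel2), 201)
    ## no calls: empty selection
    expect_length(selectWindows(call[0], grid), 0)
})

test_that("genotyping fills wild type, passes CN through, marks failed QC", {
    fx <- matrixFixture()
    grid <- buildWindowGrid(fx$chrom_lengths)
    hc <- qcHighConfidence(fx$calls, length(fx$samples))
    sel <- selectWindows(hc, grid)
    cnm <- genotypeWindows(fx$calls, sel, fx$samples)
    cn <- cnValues(cnm); prov <- cnProvenance(cnm)
    w5 <- which(GenomicRanges::start(rowRanges(cnm)) == 801)
    ## s2 carries the duplication, s1/s3 are wild type (exactly 2),
    ## s4's only overlapping call failed q0 -> missing
    expect_equal(unname(cn[w5, "s2"]), 2.6)
    expect_identical(unname(prov[w5, "s1"]), "wildtype_fill")
    expect_identical(unname(cn[w5, "s1"]), 2)
    expect_true(is.na(cn[w5, "s4"]))
    expect_identical(unname(prov[w5, "s4"]), "failed_qc")
    ## extreme low CN passes through unchanged
    df <- fx$calls_df; df$cn[1] <- 0.08
    cnm2 <- genotypeWindows(makeCalls(df), sel, fx$samples)
    expect_equal(unname(cnValues(cnm2)[1, "s1"]), 0.08)
})

test_that("multi-call cells pick the largest overlap, then smaller start", {
    grid <- buildWindowGrid(c(`1` = 600))
    win <- grid[2]  # 201..400
    df <- data.frame(
        sample_id = "s1", sv_type = "deletion", chrom = "1",
        start = c(101, 301), end = c(300, 1000) - c(0, 400),
        cn = c(1.5, 0.5), p_value = 1e-9, q0 = 0,
        stringsAsFactors = FALSE)
    ## call A overlaps 201..300 (100 bp), call B overlaps 301..400 (...)
    df$start <- c(101, 301); df$end <- c(300, 600)
    cnm <- genotypeWindows(makeCalls(df), win, "s1")
    expect_equal(unname(cnValues(cnm)[1, 1]), 1.5)  # equal 100-bp overlap: smaller start
    ## make B the larger overlap: B wins
    df$start <- c(101, 251)
    cnm2 <- genotypeWindows(makeCalls(df), win, "s1")
    expect_equal(unname(cnValues(cnm2)[1, 1]), 0.5)
})

test_that("adjacent identical columns merge; gaps and differences do not", {
    samples <- c("a", "b")
    gr <- GRanges("1", IRanges::IRanges(c(1, 201, 401, 801),
                                        c(200, 400, 600, 1000)))
    cn <- rbind(c(1, 2), c(1, 2), c(1, 2), c(1, 2))
    prov <- matrix("called", 4, 2)
    prov[cn == 2] <- "wildtype_fill"
    cnm <- CNMatrix(cn, prov, gr, samples)
    m <- mergeAdjacent(cnm)
    ## windows 1-3 adjacent and identical -> one 600-bp CNV; window at 801
    ## is identical but separated by an unselected window -> stays apart
    expect_equal(nrow(m), 2)
    expect_equal(GenomicRanges::width(rowRanges(m)), c(600, 200))
    expect_equal(mcols(rowRanges(m))$n_windows, c(3L, 1L))

    ## a single differing sample splits the run
    cn2 <- rbind(c(1, 2), c(1, 1.5), c(1, 2))
    prov2 <- matrix("called", 3, 2); prov2[cn2 == 2] <- "wildtype_fill"
    cnm2 <- CNMatrix(cn2, prov2, gr[1:3], samples)
    expect_equal(nrow(mergeAdjacent(cnm2)), 3)

    ## missing matches only missing
    cn3 <- rbind(c(1, NA), c(1, NA), c(1, 2))
    prov3 <- matrix("called", 3, 2)
    prov3[is.na(cn3)] <- "failed_qc"; prov3[which(cn3 == 2)] <- "wildtype_fill"
    cnm3 <- CNMatrix(cn3, prov3, gr[1:3], samples)
    m3 <- mergeAdjacent(cnm3)
    expect_equal(nrow(m3), 2)
    expect_true(is.na(cnValues(m3)[1, "b"]))

    ## idempotence
    m_again <- mergeAdjacent(m)
    expect_equal(nrow(m_again), nrow(m))
    expect_equal(cnValues(m_again), cnValues(m))
})

test_that("selected windows and high-confidence calls cover each other", {
    cfg <- simConfig(n_samples = 80, seed = 17)
    g <- simulateGenotypes(cfg)
    calls <- simulateCnvCalls(g, cfg)
    hc <- qcHighConfidence(calls, cfg$n_samples)
    grid <- buildWindowGrid(cfg$chromosome_lengths)
    sel <- selectWindows(hc, grid)
    ## every high-confidence call overlaps >= 1 selected window
    expect_true(all(GenomicRanges::countOverlaps(hc, sel) > 0))
    ## every selected window traces back to >= 1 high-confidence call
    expect_true(all(GenomicRanges::countOverlaps(sel, hc) > 0))
})

test_that("CNMatrix validity rejects contract violations", {
    gr <- GRanges("1", IRanges::IRanges(1, 200))
    expect_error(CNMatrix(matrix(1.5, 1, 1),
                          matrix("wildtype_fill", 1, 1), gr, "s1"),
                 "wildtype_fill")
    expect_error(CNMatrix(matrix(1.5, 1, 1),
                          matrix("failed_qc", 1, 1), gr, "s1"),
                 "failed_qc")
    expect_error(CNMatrix(matrix(-0.5, 1, 1),
                          matrix("called", 1, 1), gr, "s1"),
                 "non-negative")
    expect_error(CNMatrix(matrix(2, 1, 1),
                          matrix("whatever", 1, 1), gr, "s1"),
                 "provenance")
})

test_that("zero jitter and a clean caller give one merged CNV per region", {
    reg <- defaultTruthRegions(6)
    reg$breakpoint_jitter_sd <- 0
    cfg <- simConfig(n_samples = 60, regions = reg,
                     effects = defaultEffects()[0, ],
                     call_q0_fail_rate = 0, noise_call_rate = 0,
                     seed = 23)
    g <- simulateGenotypes(cfg)
    calls <- simulateCnvCalls(g, cfg)
    mats <- buildCnMatrix(calls, cfg$chromosome_lengths, rownames(g$cn))
    merged <- mats$merged
    polymorphic <- which(colSums(g$dosage > 0) > 0)
    expect_equal(nrow(merged), length(polymorphic))
    ## each merged CNV's carrier set equals the true carrier set
    reg_gr <- GRanges(reg$chrom, IRanges::IRanges(reg$start, reg$end))
    for (i in seq_len(nrow(merged))) {
        r <- GenomicRanges::findOverlaps(rowRanges(merged)[i], reg_gr,
                                         select = "first")
        truth_carriers <- rownames(g$cn)[g$dosage[, r] > 0]
        called_carriers <- colnames(cnValues(merged))[
            abs(cnValues(merged)[i, ] - 2) > 1e-9]
        expect_setequal(called_carriers, truth_carriers)
    }
})
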