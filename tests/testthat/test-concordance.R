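test_that("yield QC keeps samples at or above 30 Gbp", {
    y <- c(a = 29.9, b = 30.0, c = 45)
    qc <- coverageQc(y)
    expect_identical(qc$passed, c(FALSE, TRUE, TRUE))
    ## 15 samples, 3 below threshold: 12 remain
    set.seed(8)
    y15 <- c(runif(12, 31, 60), runif(3, 5, 29))
    names(y15) <- sprintf("pt%02d", 1:15)
    expect_equal(sum(coverageQc(y15)$passed), 12)
})

test_that("reciprocal overlap is min of both fractions", {
    a <- GRanges("1", IRanges::IRanges(1, 100))
    expect_equal(reciprocalOverlap(a, a), 1)
    b <- GRanges("1", IRanges::IRanges(51, 150))
    expect_equal(reciprocalOverlap(a, b), 0.5)
    expect_equal(reciprocalOverlap(b, a), 0.5)   # symmetric
    expect_equal(reciprocalOverlap(a, GRanges("1", IRanges::IRanges(500, 600))), 0)
    expect_equal(reciprocalOverlap(a, GRanges("2", IRanges::IRanges(1, 100))), 0)
    ## growing one interval away from the other never increases the RO
    ros <- vapply(seq(100, 400, by = 50), function(e)
        reciprocalOverlap(a, GRanges("1", IRanges::IRanges(51, 51 + e))), 0)
    expect_true(all(diff(ros) <= 1e-12))
})

test_that("call matching respects mode and CN-direction consistency", {
    short <- GRanges("1", IRanges::IRanges(1, 5000))
    lr <- GRanges("1", IRanges::IRanges(c(101, 101, 2000, 2500),
                                        c(4900, 4900, 2000, 2501)))
    mcols(lr)$sample_id <- "pt1"
    mcols(lr)$sv_type <- c("DEL", "DUP", "INS", "INV")
    mcols(lr)$genotype <- "het"
    mcols(lr)$caller <- "x"
    ## deletion: only the DEL with RO = 0.96 matches
    m <- matchCalls(short, "deletion", lr)
    expect_length(m, 1)
    expect_identical(mcols(m)$sv_type, "DEL")
    expect_equal(reciprocalOverlap(short, m), 0.96)
    ## duplication under reciprocal_50: DUP matches, the 1-bp INS does not
    m2 <- matchCalls(short, "duplication", lr)
    expect_identical(mcols(m2)$sv_type, "DUP")
    ## any_1bp mode admits the insertion cluster
    m3 <- matchCalls(short, "duplication", lr, mode = "any_1bp")
    expect_setequal(mcols(m3)$sv_type, c("DUP", "INS"))
    ## INS consistency can be switched off; INV is never consistent
    m4 <- matchCalls(short, "duplication", lr, mode = "any_1bp",
                     ins_as_dup = FALSE)
    expect_identical(mcols(m4)$sv_type, "DUP")
    expect_false("INV" %in% mcols(m3)$sv_type)
})

test_that("per-cell concordance classification covers all states", {
    gr <- GRanges("1", IRanges::IRanges(c(1001, 9001), c(3000, 11000)))
    ## rows = CNVs, columns = samples: pa carries (del, dup), pb is wild
    ## type at CNV 1 and missing at CNV 2, pc is wild type throughout
    cn <- matrix(c(1, 3,   2, NA,  2, 2), nrow = 2,
                 dimnames = list(NULL, c("pa", "pb", "pc")))
    prov <- matrix(c("called", "called", "wildtype_fill", "failed_qc",
                     "wildtype_fill", "wildtype_fill"), nrow = 2)
    cnm <- CNMatrix(cn, prov, gr)
    lr <- GRanges("1", IRanges::IRanges(c(1051, 9051), c(2950, 10950)))
    mcols(lr)$sample_id <- c("pa", "pb")
    mcols(lr)$sv_type <- c("DEL", "DEL")
    mcols(lr)$genotype <- "het"
    mcols(lr)$caller <- "x"
    yields <- c(pa = 40, pb = 40, pc = 20)
    coverage <- matrix(20, 2, 3, dimnames = list(NULL, c("pa", "pb", "pc")))
    coverage[2, 2] <- 2   # low regional coverage for (cnv2, pb)
    rec <- classifyConcordance(cnm, lr, yields, coverage)
    ## the yield-failed sample is omitted entirely
    expect_false("pc" %in% rec$sample_id)
    get <- function(i, s) rec[rec$cnv_idx == i & rec$sample_id == s, ]
    ## short deletion with a matched het DEL: concordant
    expect_identical(get(1, "pa")$classification, "concordant")
    ## short wild type with no overlapping call: concordant
    expect_identical(get(1, "pb")$classification, "concordant")
    expect_identical(get(1, "pb")$long_state, "none")
    ## short duplication but only a DEL overlaps: discordant
    expect_identical(get(2, "pa")$classification, "discordant")
    ## low regional coverage: not assessable regardless of the DEL call
    expect_identical(get(2, "pb")$classification, "not_assessable")
    expect_identical(get(2, "pb")$long_state, "low_coverage")
    ## counts satisfy the bookkeeping identity per CNV
    tab <- table(rec$classification)
    expect_equal(sum(tab), 2 * 2)

    ## wild type contradicted by an overlapping long-read deletion
    cn_wt <- matrix(2, 1, 1, dimnames = list(NULL, "pa"))
    cnm_wt <- CNMatrix(cn_wt, matrix("wildtype_fill", 1, 1), gr[1])
    rec_wt <- classifyConcordance(cnm_wt, lr, c(pa = 40),
                                  matrix(20, 1, 1,
                                         dimnames = list(NULL, "pa")))
    expect_identical(rec_wt$classification, "discordant")

    ## missing short-read genotype is never assessed
    cn_na <- matrix(NA_real_, 1, 1, dimnames = list(NULL, "pa"))
    cnm_na <- CNMatrix(cn_na, matrix("failed_qc", 1, 1), gr[1])
    rec_na <- classifyConcordance(cnm_na, lr, c(pa = 40),
                                  matrix(20, 1, 1,
                                         dimnames = list(NULL, "pa")))
    expect_identical(rec_na$classification, "not_assessable")
})

test_that("classification agrees with matchCalls on carrier cells", {
    set.seed(10)
    cfg <- validationConfig(n_del = 10, n_dup = 10, seed = 10)
    g <- singletonGenotypes(cfg)
    calls <- simulateCnvCalls(g, cfg)
    mats <- buildCnMatrix(calls, cfg$chromosome_lengths, rownames(g$cn))
    lr <- simulateLongreadCalls(g, cfg)
    reg_gr <- GRanges(cfg$regions$chrom,
                      IRanges::IRanges(cfg$regions$start, cfg$regions$end))
    hit <- GenomicRanges::findOverlaps(rowRanges(mats$merged), reg_gr,
                                       select = "first")
    rec <- classifyConcordance(mats$merged, lr$records, lr$yields,
                               lr$coverage[hit, , drop = FALSE])
    carriers <- rec[rec$short_state %in% c("deletion", "duplication") &
                        rec$classification != "not_assessable", ]
    for (k in seq_len(nrow(carriers))) {
        r <- carriers[k, ]
        sample_lr <- lr$records[mcols(lr$records)$sample_id == r$sample_id]
        m <- matchCalls(rowRanges(mats$merged)[r$cnv_idx], r$short_state,
                        sample_lr)
        expect_identical(r$classification,
                         if (length(m) > 0) "concordant" else "discordant")
    }
})

test_that("validation summary mirrors per-direction carrier accounting", {
    rec <- data.frame(
        cnv_idx = c(rep(1, 5), rep(2, 9), rep(3, 3)),
        sample_id = c(sprintf("p%d", 1:5), sprintf("p%d", 1:9),
                      sprintf("p%d", 1:3)),
        short_cn = 1,
        short_state = c(rep("deletion", 4), "wildtype",
                        rep("deletion", 8), "wildtype",
                        rep("wildtype", 3)),
        long_state = "deletion",
        classification = c(rep("concordant", 4), "concordant",
                           rep("concordant", 6), rep("not_assessable", 2),
                           "concordant", rep("concordant", 3)),
        stringsAsFactors = FALSE)
    s <- summarizeValidation(rec)
    ## CNV 1: 4 deletion carriers, all concordant -> validated
    expect_equal(s$n_del_carriers[1], 4)
    expect_equal(s$del_concordant[1], 4)
    expect_true(s$validated_100[1])
    ## CNV 2: 6 concordant, 0 discordant, 2 NA among 8 carriers -> validated
    expect_equal(s$n_del_carriers[2], 8)
    expect_equal(s$del_concordant[2], 6)
    expect_equal(s$del_na[2], 2)
    expect_true(s$validated_100[2])
    ## identity: N_C + N_D + N_NA = carriers
    expect_equal(s$del_concordant + s$del_discordant + s$del_na,
                 s$n_del_carriers)
    ## CNV 3: no carriers assessed -> not validated
    expect_false(s$validated_100[3])
    ## a single discordant carrier breaks validation
    rec$classification[1] <- "discordant"
    expect_false(summarizeValidation(rec)$validated_100[1])
})

test_that("extreme sensitivities give the expected concordance extremes", {
    cfg <- validationConfig(n_del = 20, n_dup = 20,
                            sensitivity = c(DEL = 1, DUP = 0), seed = 12)
    v <- runValidationPipeline(cfg)
    ## every represented deletion validates; no duplication does
    expect_equal(v$del_validated_frac, 1)
    expect_equal(v$dup_validated_frac, 0)
    carriers <- v$records[v$records$short_state == "duplication", ]
    expect_true(all(carriers$classification == "discordant"))
})
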