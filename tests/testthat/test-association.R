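test_that("covariate residualization removes age/sex/batch structure", {
    set.seed(1)
    n <- 1000
    age <- runif(n, 30, 75); sex <- rbinom(n, 1, 0.5)
    batch <- sample(c("b1", "b2", "b3"), n, replace = TRUE)
    ## protein identically equal to age: residuals all zero
    res <- adjustCovariates(age, age, sex, batch)
    expect_equal(res, rep(0, n), tolerance = 1e-10)
    ## protein independent of covariates keeps its variance (within 5%)
    y <- rnorm(n)
    res2 <- adjustCovariates(y, age, sex, batch)
    expect_lt(abs(var(res2) / var(y) - 1), 0.05)
    ## a single batch level is dropped with a warning, not an error
    expect_warning(res3 <- adjustCovariates(y, age, sex,
                                            rep("b1", n)), "batch")
    expect_length(res3, n)
    ## missingness propagates
    y[5] <- NA
    res4 <- adjustCovariates(y, age, sex, batch)
    expect_true(is.na(res4[5]))
    expect_false(anyNA(res4[-5]))
})

test_that("inverse normal transform matches the Blom-offset oracle", {
    v <- c(5.1, 2.0, 9.7)
    z <- inverseNormalTransform(v)
    ## oracle: ranks (2, 1, 3), qnorm((r - 3/8) / 3.25), then standardize
    pre <- qnorm((c(2, 1, 3) - 3 / 8) / (3 + 1 / 4))
    expect_equal(pre, c(0, -0.8694, 0.8694), tolerance = 1e-4)
    expect_equal(z, c(0, -1, 1), tolerance = 1e-12)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)

    ## middle value of any odd-length distinct input maps to 0
    set.seed(2)
    v7 <- sample(rnorm(7))
    z7 <- inverseNormalTransform(v7)
    expect_equal(z7[which(rank(v7) == 4)], 0, tolerance = 1e-12)

    ## idempotence on distinct values
    expect_equal(inverseNormalTransform(z7), z7, tolerance = 1e-12)

    ## ties share the average rank
    zt <- inverseNormalTransform(c(1, 1, 5, 9))
    expect_equal(zt[1], zt[2])

    ## NA stays NA, moments computed over observed values
    zna <- inverseNormalTransform(c(3, NA, 1, 7, 2))
    expect_true(is.na(zna[2]))
    expect_equal(mean(zna, na.rm = TRUE), 0, tolerance = 1e-12)

    expect_error(inverseNormalTransform(c(4, 4, 4)), "tied")
    expect_error(inverseNormalTransform(c(1, NA)), ">= 3")
})

test_that("testability needs >= 3 carriers with observed protein", {
    cn <- c(1, 1, 2, 2, 2, 1, 1, 1)
    y <- rnorm(8)
    expect_true(filterTestable(cn, y))                     # 5 carriers
    expect_false(filterTestable(c(1, 1, rep(2, 6)), y))    # 2 carriers
    expect_true(filterTestable(c(1, 1, 1, rep(2, 5)), y))  # exactly 3
    ## carriers with missing protein do not count
    y2 <- y; y2[c(1, 2, 6)] <- NA
    expect_false(filterTestable(cn, y2))                   # 5 - 3 = 2 left
    ## CN within 1e-9 of 2 is wild type; just beyond is a carrier
    expect_false(filterTestable(c(2 + 1e-12, 2 + 1e-12, 2 + 1e-12, 2),
                                rnorm(4)))
    expect_true(filterTestable(c(2.1, 1.9, 2.001, 2), rnorm(4)))
})

test_that("association fit matches closed-form OLS and lm", {
    ## tiny closed form: cn = (0,1,2), y = (0,0,3) with df = 1
    rec <- fitAssociation(c(0, 1, 2), c(0, 0, 3))
    expect_equal(rec$beta, 1.5, tolerance = 1e-12)
    expect_equal(rec$se, sqrt(0.75), tolerance = 1e-12)
    expect_equal(rec$p_value, 1 / 3, tolerance = 1e-12)
    expect_equal(rec$n_used, 3)

    ## exact linear relation: zero residuals, exact beta
    cn <- c(0, 1, 2, 2, 4)
    rec2 <- fitAssociation(cn, 2 + 0.5 * cn)
    expect_equal(rec2$beta, 0.5, tolerance = 1e-12)
    expect_equal(rec2$p_value, 0, tolerance = 1e-12)

    ## against stats::lm on noisy data with PCs and missing values
    set.seed(3)
    n <- 200
    cnv <- sample(c(0, 1, 2), n, replace = TRUE, prob = c(0.1, 0.3, 0.6))
    pcs <- matrix(rnorm(n * 4), n)
    y <- 0.4 * cnv + pcs %*% c(0.2, -0.1, 0, 0.3) + rnorm(n)
    y[sample(n, 10)] <- NA
    rec3 <- fitAssociation(cnv, y, pcs, n_pcs = 4)
    ref <- summary(lm(y ~ cnv + pcs))$coefficients["cnv", ]
    expect_equal(rec3$beta, unname(ref["Estimate"]), tolerance = 1e-10)
    expect_equal(rec3$se, unname(ref["Std. Error"]), tolerance = 1e-10)
    expect_equal(rec3$p_value, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
    expect_equal(rec3$n_used, sum(!is.na(y)))
    expect_equal(rec3$n_deleted, sum(cnv[!is.na(y)] < 2))

    ## affine rescaling of the PCs leaves the CN coefficient unchanged
    pcs2 <- sweep(pcs * 13.7, 2, c(1, -2, 3, 0.5), `+`)
    rec4 <- fitAssociation(cnv, y, pcs2, n_pcs = 4)
    expect_equal(rec4$beta, rec3$beta, tolerance = 1e-10)
    expect_equal(rec4$p_value, rec3$p_value, tolerance = 1e-10)

    expect_error(fitAssociation(rep(2, 10), rnorm(10)), "CN variance")
})

test_that("the Bonferroni threshold is exactly alpha over tests", {
    expect_equal(bonferroniThreshold(1), 0.05)
    expect_equal(bonferroniThreshold(1e6), 5e-8)
    expect_equal(bonferroniThreshold(20, 0.01), 5e-4)
    expect_error(bonferroniThreshold(0))
})

test_that("the scan counts exactly the testable pairs", {
    cfg <- simConfig(n_samples = 120, regions = defaultTruthRegions(8),
                     effects = data.frame(region_id = "region05",
                                          protein_id = "prot03",
                                          beta = 0.8), seed = 13)
    pipe <- runCohortPipeline(cfg)
    merged <- pipe$matrix$merged
    cn <- cnValues(merged)
    norm <- pipe$normalized
    expected <- 0L
    for (i in seq_len(nrow(cn)))
        for (j in seq_len(ncol(norm)))
            if (filterTestable(cn[i, ], norm[, j])) expected <- expected + 1L
    expect_equal(pipe$scan$plan$n_tests_performed, expected)
    expect_equal(pipe$scan$plan$threshold, 0.05 / expected)
})

test_that("cis/trans classification uses chromosome and 2-Mbp distance", {
    win <- GRanges("3", IRanges::IRanges(98410601, 98414801))
    gene_same_near <- GRanges("3", IRanges::IRanges(99914802, 99920000))
    gene_same_far <- GRanges("3", IRanges::IRanges(100914802, 100920000))
    gene_other <- GRanges("17", IRanges::IRanges(62079953, 62097994))
    gene_overlap <- GRanges("3", IRanges::IRanges(98410000, 98412000))
    expect_identical(classifyCisTrans(win, gene_same_near), "cis")
    expect_identical(classifyCisTrans(win, gene_same_far), "trans")
    expect_identical(classifyCisTrans(win, gene_other), "trans")
    expect_identical(classifyCisTrans(win, gene_overlap), "cis")
    ## boundary: a gap of exactly 2 Mbp is trans
    gene_edge <- GRanges("3", IRanges::IRanges(98414802 + 2e6, 98414802 + 2e6 + 10))
    expect_identical(classifyCisTrans(win, gene_edge), "trans")
})

test_that("Fisher cis/trans enrichment matches hypergeometric enumeration", {
    expect_equal(fisherCisTrans(5, 5, 5, 5), 1)
    ## fully crossed table: only two extreme tables are as or more extreme
    expect_equal(fisherCisTrans(0, 10, 10, 0), 2 / choose(20, 10),
                 tolerance = 1e-12)
    ## zero margin convention
    expect_equal(fisherCisTrans(0, 0, 10, 5), 1)
    ## brute-force two-sided enumeration oracle on a small table
    bf_fisher <- function(a, b, c_, d) {
        rs1 <- a + b; cs1 <- a + c_; n <- a + b + c_ + d
        probs <- vapply(max(0, cs1 - (n - rs1)):min(rs1, cs1),
                        function(x) dhyper(x, cs1, n - cs1, rs1), 0)
        p_obs <- dhyper(a, cs1, n - cs1, rs1)
        sum(probs[probs <= p_obs * (1 + 1e-7)])
    }
    expect_equal(fisherCisTrans(3, 7, 12, 4), bf_fisher(3, 7, 12, 4),
                 tolerance = 1e-9)
})

test_that("genomic inflation is the chi-square median ratio", {
    expect_equal(genomicInflation(rep(0.5, 25)), 1)
    p1 <- rep(pchisq(1, 1, lower.tail = FALSE), 25)
    expect_equal(genomicInflation(p1), 1 / qchisq(0.5, 1),
                 tolerance = 1e-9)
    expect_equal(1 / qchisq(0.5, 1), 2.198, tolerance = 1e-3)
    expect_error(genomicInflation(rep(0.5, 5)), "20")
})

test_that("inflation comparison is a two-group Kruskal-Wallis", {
    expect_equal(compareInflation(c(1, 2, 3), c(1, 2, 3)), 1,
                 tolerance = 1e-9)
    p <- compareInflation(c(1, 2, 3), c(4, 5, 6))
    ## rank-statistic oracle: H = 3.857, p = P(chi2_1 > H)
    expect_equal(p, pchisq(3.857143, 1, lower.tail = FALSE),
                 tolerance = 1e-4)
    ## jointly permuting group labels leaves p unchanged
    expect_equal(compareInflation(c(4, 5, 6), c(1, 2, 3)), p)
    expect_error(compareInflation(1, c(1, 2)), ">= 2")
})
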