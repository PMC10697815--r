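## CNV-protein association.
##
## Proteins are pre-residualized on age, sex and batch, then mapped through
## the rank-based inverse normal transformation (Blom offset 3/8, followed
## by exact standardization to mean 0 / SD 1).  Each testable
## (CNV, protein) pair is fit by ordinary least squares of the normalized
## protein on the continuous CN plus the leading genetic principal
## components; a pair is testable when at least `carrier_min` samples have
## both CN different from 2 and an observed protein value.  The
## significance threshold is the family-wise alpha divided by the exact
## number of tests performed.

#' Residualize a protein on age, sex and batch
#'
#' Ordinary least squares of the protein on age, sex and batch indicators;
#' missing values are propagated to the residuals.  A covariate without
#' variation (e.g. a single batch level) is dropped with a warning rather
#' than producing a singular fit.
#'
#' @param y numeric protein values (may contain `NA`).
#' @param age,sex numeric covariates.
#' @param batch batch labels (treated as categorical).
#' @return numeric residual vector aligned with `y`.
#' @export
adjustCovariates <- function(y, age, sex, batch) {
    stopifnot(length(age) == length(y), length(sex) == length(y),
              length(batch) == length(y))
    if (sum(!is.na(y)) < 10) stop("need >= 10 non-missing protein values")
    df <- data.frame(y = y, age = age, sex = sex,
                     batch = factor(batch))
    terms <- c("age", "sex", "batch")
    usable <- !is.na(y)
    keep <- vapply(terms, function(tm) {
        v <- df[[tm]][usable]
        ok <- length(unique(v[!is.na(v)])) > 1
        if (!ok) warning(sprintf("covariate '%s' has no variation; dropped",
                                 tm), call. = FALSE)
        ok
    }, TRUE)
    rhs <- if (any(keep)) paste(terms[keep], collapse = " + ") else "1"
    fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = df,
                     na.action = stats::na.exclude)
    as.numeric(stats::residuals(fit))
}

#' Rank-based inverse normal transformation
#'
#' Maps ranks (average rank for ties) through the standard normal quantile
#' at `(r - 3/8) / (n + 1/4)` and then standardizes the result (subtract
#' the mean, divide by the sample SD with the n-1 denominator) so that the
#' non-missing values have mean 0 and SD 1 exactly.
#'
#' @param values numeric vector with >= 3 non-missing values; missing
#'   values stay missing.
#' @return the transformed vector.
#' @export
inverseNormalTransform <- function(values) {
    obs <- !is.na(values)
    n <- sum(obs)
    if (n < 3) stop("need >= 3 non-missing values")
    v <- values[obs]
    if (length(unique(v)) == 1)
        stop("all values tied: no order information")
    r <- rank(v, ties.method = "average")
    z <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
    z <- (z - mean(z)) / stats::sd(z)
    out <- rep(NA_real_, length(values))
    out[obs] <- z
    out
}

#' Normalize a protein matrix for association testing
#'
#' Applies [adjustCovariates()] then [inverseNormalTransform()] to each
#' protein column.
#'
#' @param proteins samples x proteins numeric matrix.
#' @param covariates data.frame with `age`, `sex`, `batch` aligned with the
#'   rows of `proteins`.
#' @return matrix of the same shape, each column mean 0 / SD 1 over its
#'   non-missing entries.
#' @export
normalizeProteins <- function(proteins, covariates) {
    stopifnot(nrow(proteins) == nrow(covariates))
    out <- proteins
    for (j in seq_len(ncol(proteins))) {
        res <- adjustCovariates(proteins[, j], covariates$age,
                                covariates$sex, covariates$batch)
        out[, j] <- inverseNormalTransform(res)
    }
    out
}

#' Is a (CNV, protein) pair testable?
#'
#' @param cn per-sample CN values for one CNV (may contain `NA`).
#' @param y per-sample protein values (may contain `NA`).
#' @param carrier_min minimum number of samples with CN different from 2
#'   (|CN - 2| > 1e-9) and an observed protein value.
#' @return `TRUE` iff at least `carrier_min` such samples exist.
#' @export
filterTestable <- function(cn, y, carrier_min = 3) {
    stopifnot(length(cn) == length(y))
    sum(!is.na(cn) & abs(cn - 2) > 1e-9 & !is.na(y)) >= carrier_min
}

## OLS fit returning coefficient table for the second column (the CN or
## first predictor of interest).  X includes the intercept.
.ols <- function(X, y, coef_idx = 2L) {
    fit <- stats::lm.fit(X, y)
    if (fit$rank < ncol(X)) stop("singular design")
    df <- length(y) - fit$rank
    if (df < 1) stop("no residual degrees of freedom")
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / df
    R <- qr.R(fit$qr)
    XtXinv <- chol2inv(R)
    se <- sqrt(sigma2 * diag(XtXinv))
    beta <- fit$coefficients
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df)
    list(beta = beta[coef_idx], se = se[coef_idx], p = p[coef_idx],
         df = df, all_beta = beta, all_se = se, all_p = p,
         residuals = fit$residuals)
}

#' Fit the CNV-protein association model
#'
#' Ordinary least squares of the normalized protein on an intercept, the
#' continuous CN, and the first `n_pcs` genetic principal components, with
#' listwise deletion of missing values.  The reported effect, standard
#' error and two-sided t-test p-value are for the CN coefficient.
#'
#' @param cn per-sample CN vector.
#' @param y per-sample normalized protein vector.
#' @param pcs samples x PCs matrix (or `NULL` for no PC adjustment).
#' @param n_pcs number of leading PCs to include (default all columns of
#'   `pcs`; the primary analysis uses 4, the sensitivity analysis 10).
#' @param extra optional matrix of further covariates (e.g. conditioning
#'   SNP allele counts).
#' @return one-row data.frame with `beta`, `se`, `p_value`, `n_used`,
#'   `n_carriers`, `n_deleted`, `n_duplicated`.
#' @export
fitAssociation <- function(cn, y, pcs = NULL, n_pcs = NULL, extra = NULL) {
    stopifnot(length(cn) == length(y))
    if (!is.null(pcs)) {
        pcs <- as.matrix(pcs)
        if (is.null(n_pcs)) n_pcs <- ncol(pcs)
        stopifnot(n_pcs <= ncol(pcs))
        pcs <- pcs[, seq_len(n_pcs), drop = FALSE]
    }
    use <- !is.na(cn) & !is.na(y)
    if (!is.null(pcs)) use <- use & stats::complete.cases(pcs)
    if (!is.null(extra)) {
        extra <- as.matrix(extra)
        use <- use & stats::complete.cases(extra)
    }
    cnu <- cn[use]; yu <- y[use]
    if (length(unique(cnu)) < 2) stop("no CN variance")
    X <- cbind(`(Intercept)` = 1, cn = cnu)
    if (!is.null(pcs)) X <- cbind(X, pcs[use, , drop = FALSE])
    if (!is.null(extra)) X <- cbind(X, extra[use, , drop = FALSE])
    f <- .ols(X, yu)
    carriers <- abs(cnu - 2) > 1e-9
    data.frame(beta = f$beta, se = f$se, p_value = f$p,
               n_used = length(yu), n_carriers = sum(carriers),
               n_deleted = sum(cnu < 2 - 1e-9),
               n_duplicated = sum(cnu > 2 + 1e-9))
}

#' Family-wise Bonferroni threshold
#'
#' @param n_tests number of tests performed after testability filtering.
#' @param alpha_family family-wise significance level.
#' @return exactly `alpha_family / n_tests`.
#' @export
bonferroniThreshold <- function(n_tests, alpha_family = 0.05) {
    stopifnot(n_tests >= 1)
    alpha_family / n_tests
}

#' Scan all (merged CNV, protein) pairs for association
#'
#' Applies [filterTestable()] and [fitAssociation()] to every pair; counts
#' of tests performed and the resulting Bonferroni threshold are returned
#' alongside the per-pair records (the test plan).
#'
#' @param cnm merged [CNMatrix-class] (rows are the CNV units tested).
#' @param proteins samples x proteins matrix of normalized values, rows
#'   aligned with the columns of `cnm`.
#' @param pcs samples x PCs matrix.
#' @param n_pcs number of PCs included in the model.
#' @param carrier_min testability filter.
#' @param alpha_family family-wise significance level.
#' @return list with `results` (data.frame: `cnv_idx`, `chrom`, `start`,
#'   `end`, `protein_id`, `beta`, `se`, `p_value`, `n_used`, `n_carriers`,
#'   `n_deleted`, `n_duplicated`) and `plan` (list: `n_tests_performed`,
#'   `alpha_family`, `threshold`, `carrier_min`, `n_pcs`).
#' @export
associationScan <- function(cnm, proteins, pcs = NULL, n_pcs = 4,
                            carrier_min = 3, alpha_family = 0.05) {
    stopifnot(identical(colnames(cnValues(cnm)), rownames(proteins)))
    cn <- cnValues(cnm)
    rr <- rowRanges(cnm)
    chrom <- as.character(GenomeInfoDb::seqnames(rr))
    st <- GenomicRanges::start(rr); en <- GenomicRanges::end(rr)
    if (!is.null(pcs)) {
        pcs <- as.matrix(pcs)[, seq_len(n_pcs), drop = FALSE]
        pc_ok <- stats::complete.cases(pcs)
    } else pc_ok <- rep(TRUE, ncol(cn))
    prot_ok <- !is.na(proteins)
    cap <- nrow(cn) * ncol(proteins)
    out <- list(beta = numeric(cap), se = numeric(cap),
                p_value = numeric(cap), n_used = integer(cap),
                n_carriers = integer(cap), n_deleted = integer(cap),
                n_duplicated = integer(cap), cnv_idx = integer(cap),
                protein_id = character(cap))
    n_tests <- 0L
    k <- 0L
    for (i in seq_len(nrow(cn))) {
        cni <- cn[i, ]
        cn_ok <- !is.na(cni)
        carrier <- cn_ok & abs(cni - 2) > 1e-9
        for (j in seq_len(ncol(proteins))) {
            if (sum(carrier & prot_ok[, j]) < carrier_min) next
            n_tests <- n_tests + 1L
            use <- cn_ok & prot_ok[, j] & pc_ok
            cnu <- cni[use]
            if (length(unique(cnu)) < 2) next  # no CN variance: untestable fit
            k <- k + 1L
            X <- cbind(1, cnu)
            if (!is.null(pcs)) X <- cbind(X, pcs[use, , drop = FALSE])
            f <- .ols(X, proteins[use, j])
            out$beta[k] <- f$beta
            out$se[k] <- f$se
            out$p_value[k] <- f$p
            out$n_used[k] <- length(cnu)
            out$n_carriers[k] <- sum(abs(cnu - 2) > 1e-9)
            out$n_deleted[k] <- sum(cnu < 2 - 1e-9)
            out$n_duplicated[k] <- sum(cnu > 2 + 1e-9)
            out$cnv_idx[k] <- i
            out$protein_id[k] <- colnames(proteins)[j]
        }
    }
    idx <- seq_len(k)
    results <- data.frame(
        beta = out$beta[idx], se = out$se[idx],
        p_value = out$p_value[idx], n_used = out$n_used[idx],
        n_carriers = out$n_carriers[idx], n_deleted = out$n_deleted[idx],
        n_duplicated = out$n_duplicated[idx],
        cnv_idx = out$cnv_idx[idx], chrom = chrom[out$cnv_idx[idx]],
        start = st[out$cnv_idx[idx]], end = en[out$cnv_idx[idx]],
        protein_id = out$protein_id[idx], stringsAsFactors = FALSE)
    plan <- list(n_tests_performed = n_tests, alpha_family = alpha_family,
                 threshold = if (n_tests > 0)
                     bonferroniThreshold(n_tests, alpha_family) else NA_real_,
                 carrier_min = carrier_min, n_pcs = n_pcs)
    list(results = results, plan = plan)
}

#' Classify an association as cis or trans
#'
#' Cis iff the CNV window and the protein's coding gene are on the same
#' chromosome and their minimal bp distance (0 when overlapping) is below
#' `max_dist`; otherwise trans.
#'
#' @param window `GRanges` of the CNV (length 1 or vectorized against
#'   `gene`).
#' @param gene `GRanges` of the protein's coding gene.
#' @param max_dist cis distance bound in bp.
#' @return character vector `"cis"` / `"trans"` (`NA` when the gene
#'   location is unknown).
#' @export
classifyCisTrans <- function(window, gene, max_dist = 2e6) {
    n <- max(length(window), length(gene))
    window <- rep(window, length.out = n)
    gene <- rep(gene, length.out = n)
    same <- as.character(GenomeInfoDb::seqnames(window)) ==
        as.character(GenomeInfoDb::seqnames(gene))
    out <- rep("trans", n)
    if (any(same)) {
        d <- suppressWarnings(GenomicRanges::distance(
            window[same], gene[same], ignore.strand = TRUE))
        out[same][!is.na(d) & d < max_dist] <- "cis"
    }
    out
}

#' Fisher's exact test of cis/trans enrichment
#'
#' Two-sided Fisher's exact test on the 2x2 table of cis/trans counts for
#' CNV associations vs SNP associations, two-sidedness by summing all
#' tables with point probability at most that observed.  A zero margin
#' gives p = 1.
#'
#' @param cnv_cis,cnv_trans,snp_cis,snp_trans non-negative counts.
#' @return the two-sided p-value.
#' @export
fisherCisTrans <- function(cnv_cis, cnv_trans, snp_cis, snp_trans) {
    m <- matrix(c(cnv_cis, cnv_trans, snp_cis, snp_trans), nrow = 2,
                byrow = TRUE)
    stopifnot(all(m >= 0))
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
    stats::fisher.test(m)$p.value
}

#' Genomic inflation factor
#'
#' lambda = median of the chi-square(1) quantiles of the observed
#' p-values, divided by the chi-square(1) median (0.4549364).
#'
#' @param p_values vector of >= 20 p-values.
#' @return lambda.
#' @export
genomicInflation <- function(p_values) {
    p_values <- p_values[!is.na(p_values)]
    stopifnot(length(p_values) >= 20)
    chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
    stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Compare inflation factors between protein groups
#'
#' Kruskal-Wallis rank-sum test (two groups; equivalent to a Wilcoxon
#' rank-sum with tie correction) of the per-protein inflation factors of
#' proteins with significant associations against those without.
#'
#' @param lambdas_with_hits,lambdas_without numeric vectors, each of
#'   length >= 2.
#' @return the test p-value.
#' @export
compareInflation <- function(lambdas_with_hits, lambdas_without) {
    if (length(lambdas_with_hits) < 2 || length(lambdas_without) < 2)
        stop("each group needs >= 2 values")
    stats::kruskal.test(list(lambdas_with_hits, lambdas_without))$p.value
}
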