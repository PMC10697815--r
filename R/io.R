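## File formats and the package coordinate convention.
##
## Internally every interval is a GRanges in the native Bioconductor
## convention (1-based, closed).  At the file boundaries:
##   * CNVnator-dialect call TSVs use "chrom:start-end", 1-based inclusive,
##     so they map onto GRanges coordinates unchanged;
##   * VCF POS/END are 1-based inclusive (VCF 4.2);
##   * BED is written and read as 0-based half-open (start - 1).
## Chromosome names are stored without a "chr" prefix; readers strip it.

.strip_chr <- function(x) sub("^chr", "", x)

.parse_coords <- function(coords, line_no) {
    m <- regmatches(coords, regexec("^(?:chr)?([^:]+):([0-9]+)-([0-9]+)$",
                                    coords))[[1]]
    if (length(m) != 4)
        stop(sprintf("line %d: malformed coordinate string '%s'",
                     line_no, coords), call. = FALSE)
    list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

#' Read a CNVnator-dialect CNV call table
#'
#' The dialect is a headerless whitespace-separated table with columns
#' `sv_type` (`deletion`/`duplication`), `coordinates`
#' (`chrom:start-end`, 1-based inclusive), `size` (bp), `cn` (real-valued
#' copy number, 2 = diploid), `p_value` (one-sample t-test of the regional
#' vs global read-depth signal) and `q0` (fraction of low-quality/ambiguous
#' alignments in the call region).  A 7-column variant carries `sample_id`
#' as the first column; for the 6-column variant the sample identifier is
#' taken from the `sample_id` argument.
#'
#' @param path path to the TSV file.
#' @param sample_id sample identifier used when the file has no sample
#'   column; defaults to the file's base name without extension.
#' @param dialect currently only `"cnvnator_tsv"`.
#'
#' @return A [GenomicRanges::GRanges] of calls with metadata columns
#'   `sample_id`, `sv_type`, `cn`, `p_value`, `q0`.
#' @details The `size` column is cross-checked against the interval width;
#'   on mismatch a warning is raised and the interval wins.  Invariant
#'   violations (q0 outside `[0,1]`, p outside `(0,1]`, a deletion with
#'   CN >= 2 or duplication with CN <= 2) are parse errors naming the line.
#' @export
readCnvCalls <- function(path, sample_id = NULL, dialect = "cnvnator_tsv") {
    dialect <- match.arg(dialect)
    stopifnot(file.exists(path))
    if (is.null(sample_id))
        sample_id <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(.empty_calls())
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (!all(nf %in% c(6L, 7L)))
        stop(sprintf("line %d: expected 6 or 7 fields, found %d",
                     which(!nf %in% c(6L, 7L))[1],
                     nf[!nf %in% c(6L, 7L)][1]), call. = FALSE)
    rows <- lapply(seq_along(fields), function(i) {
        f <- fields[[i]]
        if (length(f) == 7L) {
            sid <- f[1]; f <- f[-1]
        } else sid <- sample_id
        co <- .parse_coords(f[2], i)
        rec <- list(sample_id = sid, sv_type = f[1], chrom = co$chrom,
                    start = co$start, end = co$end,
                    size = as.numeric(f[3]), cn = as.numeric(f[4]),
                    p_value = as.numeric(f[5]), q0 = as.numeric(f[6]))
        if (!rec$sv_type %in% c("deletion", "duplication"))
            stop(sprintf("line %d: unknown sv_type '%s'", i, rec$sv_type),
                 call. = FALSE)
        if (any(is.na(c(rec$size, rec$cn, rec$p_value, rec$q0))))
            stop(sprintf("line %d: non-numeric field", i), call. = FALSE)
        if (rec$q0 < 0 || rec$q0 > 1)
            stop(sprintf("line %d: q0 = %g outside [0, 1]", i, rec$q0),
                 call. = FALSE)
        if (rec$p_value <= 0 || rec$p_value > 1)
            stop(sprintf("line %d: p_value = %g outside (0, 1]",
                         i, rec$p_value), call. = FALSE)
        if (rec$end <= rec$start - 1)
            stop(sprintf("line %d: empty interval", i), call. = FALSE)
        if (rec$sv_type == "deletion" && rec$cn >= 2)
            stop(sprintf("line %d: deletion with cn = %g (must be < 2)",
                         i, rec$cn), call. = FALSE)
        if (rec$sv_type == "duplication" && rec$cn <= 2)
            stop(sprintf("line %d: duplication with cn = %g (must be > 2)",
                         i, rec$cn), call. = FALSE)
        width <- rec$end - rec$start + 1
        if (rec$size != width)
            warning(sprintf(
                "line %d: size %g disagrees with interval width %g; using the interval",
                i, rec$size, width), call. = FALSE)
        rec
    })
    gr <- GenomicRanges::GRanges(
        vapply(rows, `[[`, "", "chrom"),
        IRanges::IRanges(vapply(rows, `[[`, 0, "start"),
                         vapply(rows, `[[`, 0, "end")))
    mcols(gr)$sample_id <- vapply(rows, `[[`, "", "sample_id")
    mcols(gr)$sv_type <- vapply(rows, `[[`, "", "sv_type")
    mcols(gr)$cn <- vapply(rows, `[[`, 0, "cn")
    mcols(gr)$p_value <- vapply(rows, `[[`, 0, "p_value")
    mcols(gr)$q0 <- vapply(rows, `[[`, 0, "q0")
    gr
}

.empty_calls <- function() {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$sample_id <- character(0)
    mcols(gr)$sv_type <- character(0)
    mcols(gr)$cn <- numeric(0)
    mcols(gr)$p_value <- numeric(0)
    mcols(gr)$q0 <- numeric(0)
    gr
}

#' Write CNV calls in the CNVnator TSV dialect
#'
#' Inverse of [readCnvCalls()]; emits the 7-column variant (with
#' `sample_id`) so that multi-sample cohorts round-trip through one file.
#'
#' @param calls `GRanges` with metadata columns `sample_id`, `sv_type`,
#'   `cn`, `p_value`, `q0`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCnvCalls <- function(calls, path) {
    num <- function(x) sprintf("%.17g", x)
    lines <- if (length(calls) == 0) character(0) else paste(
        mcols(calls)$sample_id,
        mcols(calls)$sv_type,
        sprintf("%s:%d-%d", as.character(GenomeInfoDb::seqnames(calls)),
                GenomicRanges::start(calls), GenomicRanges::end(calls)),
        GenomicRanges::width(calls),
        num(mcols(calls)$cn),
        num(mcols(calls)$p_value),
        num(mcols(calls)$q0),
        sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

.GT_MAP <- c("0/0" = "hom_ref", "0|0" = "hom_ref",
             "0/1" = "het", "1/0" = "het", "0|1" = "het", "1|0" = "het",
             "1/1" = "hom_alt", "1|1" = "hom_alt",
             "./." = "missing", ".|." = "missing", "." = "missing")

#' Read a structural-variant VCF into SV records
#'
#' Parses a VCF 4.2 with `SVTYPE` (and `END` and/or `SVLEN`) in INFO and
#' `GT` in FORMAT.  `DEL`/`DUP`/`INV` span `POS..END`; `INS` is anchored at
#' `POS` with width 1.  A record with neither `END` nor `SVLEN` (and not an
#' `INS`) is skipped; the number skipped is reported in one warning.
#'
#' @param path path to the VCF (uncompressed or bgzipped).
#' @return `GRanges` with metadata columns `sample_id`, `sv_type`
#'   (`DEL`/`DUP`/`INS`/`INV`/`BND`), `genotype` (`hom_ref`, `het`,
#'   `hom_alt`, `missing`) and `caller` (from the `##source` header if
#'   present).  Multi-sample VCFs yield one record per sample per variant.
#' @export
readSvVcf <- function(path) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    caller <- NA_character_
    src <- grep("^##source=", vcf@meta, value = TRUE)
    if (length(src) > 0) caller <- sub("^##source=", "", src[1])
    fix <- vcfR::getFIX(vcf)
    if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                          dimnames = list(NULL, names(fix)))
    n <- nrow(fix)
    svtype <- vcfR::extract.info(vcf, element = "SVTYPE")
    endv <- suppressWarnings(as.numeric(
        vcfR::extract.info(vcf, element = "END")))
    svlen <- suppressWarnings(as.numeric(
        vcfR::extract.info(vcf, element = "SVLEN")))
    pos <- as.numeric(fix[, "POS"])
    chrom <- .strip_chr(fix[, "CHROM"])
    start <- pos
    end <- rep(NA_real_, n)
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
        if (is.na(svtype[i])) { keep[i] <- FALSE; next }
        if (svtype[i] == "INS" || svtype[i] == "BND") {
            end[i] <- pos[i]
        } else if (!is.na(endv[i])) {
            end[i] <- endv[i]
        } else if (!is.na(svlen[i])) {
            end[i] <- pos[i] + abs(svlen[i]) - 1
        } else keep[i] <- FALSE
    }
    if (any(!keep))
        warning(sprintf("skipped %d record(s) with neither END nor SVLEN",
                        sum(!keep)), call. = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(gt)) gt <- matrix("./.", nrow = n, ncol = 1,
                                  dimnames = list(NULL, "sample1"))
    samples <- colnames(gt)
    recs <- list()
    for (s in samples) {
        g <- .GT_MAP[gt[, s]]
        g[is.na(g)] <- "missing"
        idx <- which(keep)
        if (length(idx) == 0) next
        gr <- GenomicRanges::GRanges(chrom[idx],
                                     IRanges::IRanges(start[idx], end[idx]))
        mcols(gr)$sample_id <- s
        mcols(gr)$sv_type <- svtype[idx]
        mcols(gr)$genotype <- unname(g[idx])
        mcols(gr)$caller <- caller
        recs[[s]] <- gr
    }
    if (length(recs) == 0) {
        gr <- GenomicRanges::GRanges()
        mcols(gr)$sample_id <- character(0)
        mcols(gr)$sv_type <- character(0)
        mcols(gr)$genotype <- character(0)
        mcols(gr)$caller <- character(0)
        return(gr)
    }
    do.call(c, unname(recs))
}

#' Write SV records as a minimal single-sample VCF 4.2
#'
#' @param records `GRanges` with metadata columns `sv_type` and `genotype`
#'   (all from one sample).
#' @param path output path.
#' @param sample_id sample column name.
#' @param caller written as the `##source` header.
#' @return `path`, invisibly.
#' @export
writeSvVcf <- function(records, path, sample_id = "sample1",
                       caller = "synthetic") {
    gt_inv <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                missing = "./.")
    header <- c(
        "##fileformat=VCFv4.2",
        sprintf("##source=%s", caller),
        '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
        '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
        '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", sample_id, sep = "\t"))
    body <- character(0)
    if (length(records) > 0) {
        svt <- mcols(records)$sv_type
        st <- GenomicRanges::start(records)
        en <- GenomicRanges::end(records)
        len <- ifelse(svt == "DEL", -(en - st + 1), en - st + 1)
        info <- ifelse(svt == "INS",
                       sprintf("SVTYPE=INS;SVLEN=%d", abs(len)),
                       sprintf("SVTYPE=%s;END=%d;SVLEN=%d", svt, en, len))
        body <- paste(as.character(GenomeInfoDb::seqnames(records)), st,
                      sprintf("sv%d", seq_along(records)), "N",
                      sprintf("<%s>", svt), ".", "PASS", info, "GT",
                      gt_inv[mcols(records)$genotype], sep = "\t")
    }
    writeLines(c(header, body), path)
    invisible(path)
}

#' Write intervals as sorted BED3
#'
#' Emits standard 0-based half-open BED, deterministically sorted by
#' (chrom, start, end).
#'
#' @param intervals `GRanges` (1-based closed, as everywhere internally).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(intervals, path) {
    if (length(intervals) == 0) {
        writeLines(character(0), path)
        return(invisible(path))
    }
    chrom <- .strip_chr(as.character(GenomeInfoDb::seqnames(intervals)))
    st <- GenomicRanges::start(intervals) - 1L
    en <- GenomicRanges::end(intervals)
    o <- order(chrom, st, en)
    writeLines(sprintf("%s\t%d\t%d", chrom[o], st[o], en[o]), path)
    invisible(path)
}

#' Read a BED file of annotation intervals (e.g. RepeatMasker)
#'
#' @param path BED3+ file.
#' @return `GRanges` in the internal 1-based closed convention, `chr`
#'   prefixes stripped.
#' @export
readBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    GenomeInfoDb::seqlevels(gr) <- .strip_chr(GenomeInfoDb::seqlevels(gr))
    gr
}

#' Read / write a samples-by-columns TSV matrix
#'
#' The first column holds sample identifiers; remaining columns are
#' numeric.  Used for protein, principal-component and depth tables.
#'
#' @param path file path.
#' @return numeric matrix with sample identifiers as row names.
#' @export
readTsvMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
    m
}

#' @rdname readTsvMatrix
#' @param m numeric matrix with sample-identifier row names.
#' @param id_col name of the identifier column written first.
#' @export
writeTsvMatrix <- function(m, path, id_col = "sample_id") {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- id_col
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read per-sample covariates (age, sex, batch)
#'
#' @param path TSV with columns `sample_id`, `age`, `sex`, `batch`.
#' @return data.frame with `batch` as character.
#' @export
readCovariates <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("sample_id", "age", "sex", "batch") %in% names(df)))
    df$batch <- as.character(df$batch)
    df
}

#' Read SNP genotypes from a VCF as an allele-count matrix
#'
#' @param path VCF with `GT` in FORMAT.
#' @return list with `dosage` (samples x variants matrix of 0/1/2, `NA` for
#'   missing genotypes) and `positions` (`GRanges` of the variant sites,
#'   names matching the dosage columns).
#' @export
readSnpVcf <- function(path) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                          dimnames = list(NULL, names(fix)))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dose <- apply(gt, c(1, 2), function(g) {
        if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
        sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- sprintf(
        "%s:%s", fix[is.na(ids) | ids == ".", "CHROM"],
        fix[is.na(ids) | ids == ".", "POS"])
    pos <- GenomicRanges::GRanges(.strip_chr(fix[, "CHROM"]),
                                  IRanges::IRanges(as.numeric(fix[, "POS"]),
                                                   width = 1))
    names(pos) <- ids
    d <- t(matrix(as.numeric(dose), nrow = nrow(gt)))
    dimnames(d) <- list(colnames(gt), ids)
    list(dosage = d, positions = pos)
}

#' Write a SNP allele-count matrix as a minimal VCF 4.2
#'
#' @param dosage samples x variants matrix of 0/1/2 allele counts (`NA`
#'   allowed).
#' @param positions `GRanges` of variant sites, one per dosage column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSnpVcf <- function(dosage, positions, path) {
    gts <- c("0/0", "0/1", "1/1")
    samples <- rownames(dosage)
    header <- c(
        "##fileformat=VCFv4.2",
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t"))
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- sprintf("snp%d", seq_len(ncol(dosage)))
    body <- vapply(seq_len(ncol(dosage)), function(j) {
        g <- ifelse(is.na(dosage[, j]), "./.", gts[dosage[, j] + 1])
        paste(c(as.character(GenomeInfoDb::seqnames(positions))[j],
                GenomicRanges::start(positions)[j], ids[j], "A", "G",
                ".", "PASS", ".", "GT", g), collapse = "\t")
    }, "")
    writeLines(c(header, body), path)
    invisible(path)
}
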