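#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits
#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps tileGenome
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqnames
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowRanges colData
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Per-cell provenance codes of a CNMatrix
#'
#' A cell in the population copy-number matrix is either a genotyped call
#' (`"called"`), a wild-type fill for a sample with no overlapping call
#' (`"wildtype_fill"`, value exactly 2), or missing because the sample's only
#' overlapping calls failed the q0 alignment-quality filter (`"failed_qc"`,
#' value `NA`).
#'
#' @keywords internal
.PROVENANCE_LEVELS <- c("called", "wildtype_fill", "failed_qc")

#' CNMatrix: population copy-number genotypes on a window grid
#'
#' An S4 container for a samples-by-windows matrix of real-valued copy
#' numbers (CN; 2 = diploid wild type), stored transposed in the
#' \linkS4class{RangedSummarizedExperiment} layout: rows are genomic windows
#' (or merged CNVs), columns are samples.  Two assays are carried:
#' \describe{
#'   \item{`cn`}{numeric matrix of CN values, `NA` where genotyping failed.}
#'   \item{`provenance`}{character matrix with values `"called"`,
#'     `"wildtype_fill"` or `"failed_qc"` recording how each cell was
#'     assigned.}
#' }
#' Validity enforces the genotyping contract: `wildtype_fill` cells equal
#' exactly 2, `failed_qc` cells are `NA`, and called cells are non-negative.
#'
#' @seealso [genotypeWindows()], [mergeAdjacent()], [cnValues()],
#'   [cnProvenance()]
#' @name CNMatrix-class
#' @aliases CNMatrix-class
#' @exportClass CNMatrix
setClass("CNMatrix", contains = "RangedSummarizedExperiment")

setValidity("CNMatrix", function(object) {
    an <- assayNames(object)
    if (!all(c("cn", "provenance") %in% an))
        return("assays 'cn' and 'provenance' are required")
    cn <- assay(object, "cn")
    pr <- assay(object, "provenance")
    if (!identical(dim(cn), dim(pr)))
        return("'cn' and 'provenance' assays must have identical dimensions")
    if (!all(pr %in% .PROVENANCE_LEVELS))
        return(sprintf("provenance values must be one of: %s",
                       paste(.PROVENANCE_LEVELS, collapse = ", ")))
    wt <- pr == "wildtype_fill"
    if (any(is.na(cn[wt])) || any(cn[wt] != 2))
        return("wildtype_fill cells must equal exactly 2")
    qc <- pr == "failed_qc"
    if (any(!is.na(cn[qc])))
        return("failed_qc cells must be NA")
    called <- pr == "called"
    if (any(is.na(cn[called])) || any(cn[called] < 0))
        return("called cells must be non-negative and non-missing")
    TRUE
})

#' Construct a CNMatrix
#'
#' @param cn numeric matrix, windows x samples, of copy-number values.
#' @param provenance character matrix of the same shape with values
#'   `"called"`, `"wildtype_fill"` or `"failed_qc"`.
#' @param rowRanges [GenomicRanges::GRanges] of the window (or merged-CNV)
#'   intervals, one per row of `cn`.
#' @param sample_ids character vector of sample identifiers; defaults to the
#'   column names of `cn`.
#'
#' @return A validated [CNMatrix-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1, 201), c(200, 400)))
#' cn <- matrix(c(2, 1, 2, 2), nrow = 2,
#'              dimnames = list(NULL, c("s1", "s2")))
#' pr <- matrix(c("wildtype_fill", "called", "wildtype_fill",
#'                "wildtype_fill"), nrow = 2)
#' cnm <- CNMatrix(cn, pr, gr)
#' cnValues(cnm)
#' @export
CNMatrix <- function(cn, provenance, rowRanges,
                     sample_ids = colnames(cn)) {
    if (is.null(sample_ids))
        sample_ids <- paste0("sample", seq_len(ncol(cn)))
    colnames(cn) <- sample_ids
    colnames(provenance) <- sample_ids
    se <- SummarizedExperiment(
        assays = list(cn = cn, provenance = provenance),
        rowRanges = rowRanges,
        colData = DataFrame(sample_id = sample_ids, row.names = sample_ids))
    new("CNMatrix", se)
}

#' @describeIn CNMatrix-class compact display with provenance tallies
#' @param object a `CNMatrix`
#' @export
setMethod("show", "CNMatrix", function(object) {
    cat(sprintf("CNMatrix: %d windows x %d samples\n",
                nrow(object), ncol(object)))
    tab <- table(factor(assay(object, "provenance"),
                        levels = .PROVENANCE_LEVELS))
    cat(sprintf("  cells: %d called, %d wildtype_fill, %d failed_qc\n",
                tab[["called"]], tab[["wildtype_fill"]],
                tab[["failed_qc"]]))
    if (nrow(object) > 0) {
        rr <- rowRanges(object)
        cat(sprintf("  span: %s:%d-%d ... %s:%d-%d\n",
                    as.character(GenomeInfoDb::seqnames(rr))[1],
                    GenomicRanges::start(rr)[1], GenomicRanges::end(rr)[1],
                    as.character(GenomeInfoDb::seqnames(rr))[nrow(object)],
                    GenomicRanges::start(rr)[nrow(object)],
                    GenomicRanges::end(rr)[nrow(object)]))
    }
    invisible(NULL)
})

#' Extract the copy-number value matrix
#'
#' @param x a [CNMatrix-class]
#' @return numeric matrix, windows x samples.
#' @export
cnValues <- function(x) assay(x, "cn")

#' Extract the per-cell provenance matrix
#'
#' @param x a [CNMatrix-class]
#' @return character matrix, windows x samples, values `"called"`,
#'   `"wildtype_fill"` or `"failed_qc"`.
#' @export
cnProvenance <- function(x) assay(x, "provenance")
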