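Package: cnvProteo
Title: Read-Depth CNV Discovery, Population CN Genotyping, and Plasma-Protein
    Association
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers copy-number variants (CNVs) from short-read
    whole-genome sequencing read-depth signals, genotypes them across a
    cohort into a 200-bp-window copy-number matrix, tests the copy numbers
    for association with plasma-protein measurements (pQTL scan with
    covariate adjustment, rank-based inverse normal transformation, and
    principal-component correction), clumps correlated significant windows
    into independent signals, and validates short-read calls against
    long-read structural-variant call sets by reciprocal overlap. Ships a
    synthetic-cohort generator with planted truth so every stage has a
    parameter-recovery test without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, GenomeWideAssociation, StructuralVariation,
    Sequencing
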