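---
title: "From read depth to protein pQTLs: the cnvProteo pipeline"
author: "cnvProteo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From read depth to protein pQTLs: the cnvProteo pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvProteo)
```

# The analysis design

`cnvProteo` implements a population CNV–proteome association design: CNVs
are discovered per sample from short-read WGS read-depth (RD) signals,
genotyped across the cohort into a window-level copy-number matrix,
tested for association with plasma-protein levels, reduced to independent
signals by LD clumping, and validated against long-read structural-variant
(SV) call sets. This vignette is the package's own account of each
model, its assumptions, and the design choices that were genuinely open.

# Read-depth calling

## The bin-size rule

RD calling bins the per-bp depth and selects, per sample, the smallest
bin size from the candidate set (70, 85, 100, 150, 200, 250) bp whose
binned mean/SD ratio lies in [4, 5]. The rationale is a power/resolution
trade-off: the deletion *t*-test needs the signal several times its
noise, while smaller bins localize breakpoints better. Under the
Poisson depth model the binned depth is Poisson(*b*λ), so
mean/SD = √(*b*λ) and the window [4, 5] corresponds to 16 ≤ *b*λ ≤ 25 —
at λ = 0.2 reads/bp the rule selects 85 bp, which our tests verify
against this closed form. Two numerical decisions:

* the bounds are **inclusive** at both ends — the verbal rule ("between
  4 and 5") does not fix strictness, and inclusivity makes the
  boundary case deterministic;
* when no candidate qualifies, the selector raises an error of class
  `binSizeError` carrying all per-candidate ratios; callers may instead
  force the largest candidate (`force_largest = TRUE`).

## Per-call statistics

Each candidate call is annotated with:

* `estimateCn()`: CN = 2 × mean(regional bins)/global mean — the factor
  by which the region's RD differs from its surroundings on the diploid
  scale. The global mean is computed **per chromosome** (RD callers
  normalize per chromosome; exact scope was an open choice). The
  statistic is exactly scale-invariant in the depth units.
* `callSignificance()`: a two-sided one-sample *t*-test of the regional
  bin depths against the global mean, computed from the *t* CDF with the
  convention *p* = 0 (mean differs) or 1 (mean equal) when the regional
  SD is zero — `stats::t.test` cannot represent that degenerate case,
  so the statistic is computed directly and `t.test` serves as the
  independent oracle in the tests. Bins (not reads) are the units of
  the test.
* `computeQ0()`: the depth-weighted mean of per-bin q0 fractions, 0 by
  convention on zero total depth.

## Segmentation

Full mean-shift partitioning of the RD signal is out of scope; the
package segments by maximal runs of ≥ 5 consecutive bins whose depth
ratio to the global mean is < 0.75 (deletion) or > 1.25 (duplication),
with a 1000-bp minimum call width (per-sample CNV reporting
conventionally starts at 1 kbp). These three thresholds are exposed as
arguments of `segmentDepth()`. The run-based segmenter is deliberately
simple: the genotyping matrix only needs calls whose intervals and CN
values are right, and parameter-recovery tests show it recovers planted
events with ≥ 80% overlap in ≥ 95% of seeds at 30× and tracks truth CN
with Spearman ρ ≥ 0.9 for ≥ 2-kbp events.

# The population CN matrix

Discovery calls pass a strict tier: *p* < α/(n_samples × m_s), where
m_s is the number of calls in that call's sample (a Bonferroni bound
over the whole discovery set), **and** q0 < 0.5. The genome is tiled
into non-overlapping 200-bp windows (`tileGenome`; the terminal window
is truncated and participates normally), and every window touched by ≥ 1
bp of ≥ 1 strict-tier call is selected. Genotyping then applies only the
q0 filter (the lenient tier): a cell takes the overlapping call's CN
(`called`), is exactly 2 when the sample has no overlapping call
(`wildtype_fill`), or is `NA` when the sample's only overlapping calls
failed q0 (`failed_qc`). Where several lenient calls overlap one window
for one sample, the call with the largest bp overlap wins, ties broken
by smaller start — the tie rule is not dictated by the design, only
that it be deterministic.

Adjacent windows (same chromosome, next start = previous end + 1) with
element-wise identical CN columns merge into one CNV unit; `NA` matches
only `NA`. Equality is **exact**, not tolerance-based: within one call
the CN value is bit-identical across its windows, and a tolerance would
change unit counts. The merge is idempotent, and the container
(`CNMatrix`, a `RangedSummarizedExperiment` with `cn` and `provenance`
assays) enforces the genotyping contract through its validity method.

# Association

Proteins are residualized on age, sex and batch (OLS; a covariate
without variation is dropped with a warning), then mapped through the
rank-based inverse normal transformation: ranks (average for ties)
through Φ⁻¹((r − 3/8)/(n + 1/4)), followed by exact standardization to
mean 0 / SD 1. The Blom offset 3/8 is a choice — the transformation
family is standard but the offset is not dictated — and the
post-standardization makes "mean = 0, SD = 1" hold exactly rather than
asymptotically. Residualization precedes the transformation (matching
the stated order "adjusted … and normalized"); the genetic principal
components instead enter the association model itself.

Each (CNV unit, protein) pair with ≥ 3 samples having CN ≠ 2
(|CN − 2| > 10⁻⁹; wild-type fills are exactly 2, so the tolerance only
guards genotyped values) and an observed protein is fit by OLS of the
normalized protein on intercept + CN + the first 4 PCs (10 in the
sensitivity analysis), with listwise deletion. The significance
threshold is exactly α/n_tests with n_tests the count of pairs passing
the carrier filter. Diagnostics: genomic inflation
λ = median(χ²₁ quantiles of the p-values)/0.4549, a two-group
Kruskal–Wallis comparison of per-protein λ, cis/trans labels (cis =
same chromosome and minimal distance < 2 Mbp to the protein's coding
gene), and a two-sided Fisher's exact test of cis/trans enrichment.

# Clumping, conditioning, repeats

Clumping is greedy per protein: the unassigned window with the smallest
p-value (ties: smaller start) leads; unassigned same-chromosome windows
with squared Spearman *R*² > 0.8 to the lead join it; windows with
*R*² < 0.1 to every lead are independent. The greedy-by-p convention is
the standard clumping algorithm; the thresholds come from the design.
Windows in the dead zone 0.1 ≤ *R*² ≤ 0.8 are **not** silently
assigned: they eventually lead their own clumps but are flagged
`correlated_unresolved` against the nearest such lead, because the two
thresholds leave their treatment genuinely open. CNV–CNV correlation
uses squared Spearman for consistency with the SNP–CNV LD measure (the
CNV–CNV estimator was unspecified). Conditional fits add SNP allele
counts as covariates, erroring on exact in-sample collinearity;
overlapping prior-GWAS hits require the same protein, *P* < 5×10⁻⁸ and
< 1 Mbp distance to the clump span.

# Long-read concordance

Samples with unique molecular yield < 30 Gbp (≈ 10×) are excluded
(30.0 passes; the bound is strict "less than"). Per (CNV, sample):
below 5× regional coverage → `not_assessable` (the regional QC bound
was declared but not quantified in the design; 5× is this package's
default, exposed as an argument); otherwise concordant iff both
technologies imply the same CN direction — short CN < 2 with a matched
DEL, short CN > 2 with a matched DUP (or INS: long-read callers report
tandem-repeat CN gains as insertion clusters; switchable off), or short
CN = 2 with no overlapping non-reference CNV-type call. Matching
requires 50% reciprocal overlap (`reciprocal_50`) or ≥ 1 bp
(`any_1bp`); INV and BND never imply a consistent CN change. Zygosity
agreement is **not** required — concordance is CN-direction only.
Per-CNV summaries count concordant/discordant/NA individuals by carrier
direction and flag `validated_100` when no carrier is discordant and at
least one carrier was assessable.

# The synthetic cohort

`simConfig()` defines the study conditions; all generators are
deterministic in (config, seed).

* **Genotypes**: diploid Hardy–Weinberg draws per region; CN = 2 +
  dosage × cn_per_allele. Realized breakpoints are truth ± rounded
  Normal(0, jitter SD), shared by both alleles of a sample — breakpoint
  variation is a sample-level feature of RD data and phase is
  unobservable there, so per-allele jitter would add structure nothing
  downstream could see.
* **Default cohort**: n = 500 samples, two 5-Mbp chromosomes, 30
  regions (1.2–5 kbp, allele frequencies 0.05–0.4, jitter SD 0/100/200
  bp), 20 proteins, 2 planted effects (β = 0.8 and −0.7 per CN unit on
  regions with AF ≥ 0.1). Protein model: planted CN effects + PC
  loadings (SD 0.2) + age/sex/batch terms + N(0, 1) noise, 2%
  missingness. These sizes keep a full pipeline run at ~2.5 s while
  leaving the planted effects ~10 SE above noise and the carrier filter
  non-trivial.
* **Calls**: each carrier yields one call on its realized interval with
  CN = truth + N(0, 0.05) kept on the correct side of 2, a strongly
  significant p-value, and q0 < 0.25 except a 3% fraction pushed to
  q0 ≥ 0.5 to exercise the `failed_qc` channel; spurious
  weak-significance calls (0.2/sample) exercise the two-tier QC.
* **Depth**: per-bp Poisson with rate mean_depth × CN/2; q0 mass is
  injected in designated regions. No GC bias or mappability structure
  is modelled — the caller statistics depend only on RD mean/SD and q0,
  so those axes would not be exercised by anything tested here.
* **SNPs**: a tag SNP per configured region copies each CNV allele with
  probability √(target R²) (fresh Bernoulli otherwise), which makes the
  allele-level correlation √(target) in expectation and lands the
  realized squared Spearman correlation within ±0.1 of the target at
  n ≥ 500.
* **Long reads**: each carrier event is emitted with probability
  sensitivity[type] with ±50-bp breakpoint jitter; duplications can be
  emitted as insertion clusters; per-sample yields and per-(region,
  sample) coverage matrices include configurable failing fractions.

What passing the synthetic suites does **not** show about real data:
the generator has no GC/mappability bias, no overlapping or nested
CNVs, no complex rearrangements (the inversion-with-duplication class
of event), no LD between distinct CNV regions, and protein effects are
exactly linear in CN. Results on real cohorts additionally depend on
alignment artefacts and assay QC that are out of scope here.

# Calibration and evaluation scenarios

* **Recovery sweep**: 20 seeds of the default cohort; success = both
  planted effects recovered below the run's exact Bonferroni threshold
  with ≤ 1 false-positive clump. A clump matches a planted effect when
  it is for the planted protein and its span lies within 2 kbp of the
  truth interval; the slack absorbs breakpoint jitter, which lets edge
  windows extend slightly beyond the planted interval.
* **Null calibration**: cohorts with all β = 0, p-values pooled across
  seeds to ≥ 10⁴ tests for a KS uniformity check. Units split from one
  region by jitter share carriers, so the tests are mildly dependent
  and the KS check is slightly anti-conservative; it is a calibration
  smoke test, not an exact size guarantee.
* **Validation scenario** (`validationConfig()`): a 12-sample
  subcohort over 150 deletion + 150 duplication rare CNVs, each carried
  by exactly one individual, with per-event long-read recall DEL = 0.95
  / DUP = 0.05. With a single carrier, a CNV validates exactly when its
  one event is recovered, so the per-CNV validated fraction estimates
  the per-event recall directly and the deletion/duplication asymmetry
  is reproduced with a comfortable margin; with multi-carrier CNVs the
  all-carriers-concordant requirement would compound (0.95^k) and
  conflate carrier counts with caller sensitivity. Fractions are
  reported over CNVs represented by ≥ 1 carrier among samples passing
  yield QC.

# Numerical choices and degenerate inputs

* Intervals are GRanges (1-based, closed) everywhere in memory; the
  CNVnator-dialect TSV is 1-based inclusive, BED is written 0-based
  half-open, VCF follows VCF 4.2. Chromosome names are stored without a
  `chr` prefix.
* The degenerate allele frequency 0 is allowed in configs (a
  monomorphic region, useful in tests); jitter SD must stay below half
  the region width so realized intervals cannot invert.
* `inverseNormalTransform` errors when all values are tied (no order
  information) and propagates missing values untouched.
* `fisherCisTrans` returns 1 on a zero margin; `spearmanR2` returns
  `NA` for constant vectors or < 3 complete pairs.
* `fitAssociation` errors on constant CN ("no CN variance") and on
  singular designs rather than silently dropping columns.

# Known limitations

* The segmenter is a thresholding substitute, not a mean-shift
  partitioner; calls at low depth or for small shallow events are less
  sensitive than a production caller's.
* One SV call set is evaluated at a time; multi-caller consensus is a
  loop left to the user.
* No kinship/mixed-model correction — the association model is plain
  OLS with PCs, as in the design being implemented.
* Sex chromosomes, GC correction and mappability masks are out of
  scope.
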