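---
title: "StimConverge: models, parameters and design choices"
author: "StimConverge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{StimConverge: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

StimConverge implements two connected analyses for bulk RNA-seq studies of
cytokine-stimulated cells: (i) an expression processing and
differential-expression chain with gene-set convergence statistics,
quantifying how far two cell types (here, adipocytes and macrophages
treated with IFN-beta and/or LPS) move toward a shared transcriptional
state; and (ii) a resampling-based test that asks which transcription
factors plausibly regulate a gene set, by overlapping the set's promoters
with a library of ChIP-seq/DNase-seq peak datasets against an empirical
null built from size-matched random promoter draws. This vignette explains
the models, the tunable parameters, what the synthetic-data generator does
and does not emulate, and the choices made where the procedure definitions
left room.

# The expression processing chain

The pipeline starts from gene-level counts (alignment and read-level
quantification are out of scope). Processing is a strict state machine,
`raw -> thresholded -> normalized -> baselined`, enforced by the
`ExpressionMatrix` class:

1. **RPKM** (`computeRpkm`): `count / ((length/1000) * (total/1e6))`,
   with `total` the sample's summed counts. Units: reads per kilobase of
   transcript per million mapped reads.
2. **Flooring at 1** (`thresholdRpkm`): values below 1 RPKM are replaced
   by 1. Thresholding *floors* rather than discards: flooring prevents
   log-ratios of barely-detected genes from dominating the normalization
   medians while keeping the gene universe intact; discarding remains
   possible by passing `floor = NULL` to `processExpression`.
3. **Median-of-ratios normalization** (`computeNormFactors`,
   `applyNormalization`): each gene is divided by its geometric mean
   across samples; a sample's normalization factor (NF) is the
   within-sample median of those ratios; the sample's values are divided
   by its NF. Genes with a zero in any sample are excluded from the
   median (after flooring none remain; the rule matters only when
   thresholding is skipped). Wherever a median is taken over an even
   count, it is the mean of the two central order statistics.
4. **Baselining** (`baselineToMedian`): log2, then subtraction of each
   gene's median across all samples. "Baselined to the median" is
   implemented as *per-gene* centering rather than a global-median shift:
   per-gene centering is what makes cross-sample heat maps and sample PCA
   of the baselined values meaningful, and it leaves every gene with
   median exactly zero (odd sample counts).
5. **Expressed-gene filter** (`expressionFilter`): a gene is kept if
   there exists one (cell type, treatment) condition in which *every*
   sample has raw RPKM strictly above 3. The filter deliberately uses
   raw, pre-normalization RPKM, and the inequality is strict: a gene
   sitting exactly at the cutoff in all samples is dropped.

# Differential expression

Per gene, a fixed-effects two-way ANOVA on the baselined log2 values with
factors cell type and treatment, and their interaction when replication
permits. The implementation projects all genes at once onto the QR bases
of the nested design matrices (intercept, +cell type, +treatment,
+interaction) and forms sequential sums of squares; on balanced designs
this is the classical orthogonal decomposition, and it is verified against
`stats::aov` gene by gene in the tests. Conventions:

- The interaction is retained only when the full model leaves at least 4
  residual degrees of freedom; otherwise an additive model is fitted and a
  warning is emitted. A design with no residual degrees of freedom at all
  is an error, not a silent degenerate fit.
- Genes with zero residual variance get p = 1 for every term.
- The p-value fed into FDR control ("omnibus") is the treatment-term p by
  default; the full-model p is available via `omnibus = "full"`. The
  choice is recorded in the result's metadata.
- FDR control is Benjamini-Hochberg across genes (`bhAdjust`, the
  standard step-up rule). BH is the default procedure wherever "FDR
  corrected" is not further specified.
- Fold changes are linear-scale ratios of mean *normalized* RPKM in a
  (cell type, treatment) group over the same cell type's untreated (NS)
  mean, reported as `max(r, 1/r)` with a direction sign. Fold changes are
  not computed on baselined values, which are median-centered logs.
- A gene is called differential in a group when `q < 0.05` **and**
  `fold change > 1.5`, both strict (`callDifferential`).

With the default q and FC gates, a gene whose treatment term is
significant anywhere can enter any group's called set if its
group-specific fold change clears 1.5; the per-group fold-change gate is
what differentiates the groups.

# Convergence statistics

- `topExpressed` ranks genes by mean normalized RPKM in one cell type's
  untreated samples ("most highly expressed at baseline"), with
  deterministic lexicographic tie-breaks.
- `overlapStats` reports both shared-percentage conventions, because
  bracketed percentages of the form "2033 [30.4%]" do not identify their
  denominator: `jaccard_pct` (100·|A∩B|/|A∪B|, the primary convention)
  and `sum_pct` (100·|A∩B|/(|A|+|B|)). For the one fully checkable
  worked case — two 2500-gene sets sharing 35 genes — both round to
  0.7%, so the ambiguity does not affect that anchor. Percentages are
  kept at full precision and rounded only for reporting (one decimal).
- `pcaSamples` projects samples onto the eigenvectors of the
  gene-centered covariance of the baselined values, with no additional
  scaling (baselining already centers genes); each component's sign is
  fixed so its largest-magnitude loading is positive.
- `centroidDistance` reports the Euclidean distance between the two cell
  types' centroids within a condition, both on one designated component
  and on the top-2 component plane. The plane distance is the robust
  summary: which single component captures the cell-type axis depends on
  how treatment and lineage variance compare in a given dataset.

# The enrichment test

For a gene set G and a peak dataset D:

1. **Promoter windows** (`promoterWindows`): strand-aware windows around
   each TSS. In 0-based half-open coordinates a plus-strand TSS `t` gives
   `[t - upstream, t + downstream)`; a minus-strand TSS gives the mirror
   `[t - downstream + 1, t + upstream + 1)`, the same length. The three
   conventional definitions are (-1000, +500), (-1000, +1000) and
   (-2000, +1). Windows are clamped to chromosome bounds.
2. **Observed overlap** (`observedOverlap`): the number of input windows
   sharing at least one base with at least one peak; a window overlapping
   several peaks counts once.
3. **Empirical null** (`sampleNull`): 2000 iterations, each drawing
   |G| promoter windows uniformly *without replacement* from the universe
   of all annotated promoters under the same window definition (thus
   matched in both region count and per-region length), recording the
   overlap. The input's own promoters are not excluded from the universe;
   nothing in the procedure's definition excludes them, and keeping them
   makes the null exchangeable with the input draw. Because regions are
   counted independently, the per-promoter overlap indicator is
   precomputed once and summed over each drawn index set — algebraically
   identical to re-running the overlap count per draw, and what makes
   2000 iterations cheap.
4. **Z and P** (`zPFromNull`): `z = (observed - mean)/sd` with the n-1
   denominator over the null samples, and a one-sided upper-tail
   standard-normal p by default — the test is used to rank *enriched*
   regulators; a two-sided option exists. A degenerate null (sd = 0)
   yields z = 0, p = 0.5 when the observation equals the null mean, and
   otherwise an infinite-z sentinel with p floored at 1e-300 (enrichment)
   or 1 (depletion) plus an explicit `degenerate` flag, rather than
   whatever floating point would produce.
5. **Library ranking** (`enrichLibrary`): every (dataset, window) pair is
   tested; BH-adjusted q is computed across the dataset library within
   each window (510 simultaneous tests deserve an explicit multiplicity
   stance; the raw p is always reported alongside), and results are
   sorted by z within window. Per-dataset RNG streams derive
   deterministically from the master seed and the dataset/window labels,
   so the full table is reproducible and invariant to dataset order.

# The synthetic-data generator

`simulationConfig()` encodes the emulated study design: 2 cell types
(adipocyte, macrophage) x 4 treatments (NS, IFNB, LPS, IFNB_LPS) with NS
as baseline. Counts are negative binomial with mean
`2^(base + effects) * length/1000 * scale` and configurable dispersion
(default 0.05, typical for bulk RNA-seq; 0 gives Poisson); per-gene
baselines are N(5, 1.5) on the log2 scale and gene lengths uniform on
[500, 10000] bp. Replicates default to n = 3 per condition for stable
ANOVA; `studyLike = TRUE` reproduces the emulated design's n = 2, which
is legal but fragile and is exercised in the tests.

The planted programs, all disjoint:

- **Identity programs** (100 genes per cell type, +4 log2): lineage
  markers high in one cell type under all treatments.
- **Shared response programs** (IFNB: 60, LPS: 40 genes, +2 log2):
  induced in *both* cell types by one stimulus, alone or combined.
- **Private response programs** (IFNB: 60 genes in adipocytes, LPS: 80 in
  macrophages, +2 log2): induced by one stimulus in one cell type,
  reflecting the asymmetry of interferon versus TLR responsiveness.
- **Dormant convergence program** (500 genes, +2.5 log2): induced in both
  cell types *only* under the combined treatment.
- **Identity attenuation** (0.5): under the combined treatment the
  identity effects are halved. A program induced equally in both cell
  types moves both centroids together and cannot by itself shrink the
  cross-cell-type expression distance; convergence of the *transcriptome*
  (as opposed to of the differential gene lists) requires the lineage
  programs to yield, emulating stimulated cells converging toward a
  shared activation state. With these defaults the set algebra gives
  combined-treatment Jaccard ≈ 64% versus ≈ 50% (IFNB) and ≈ 33% (LPS),
  and the squared cross-cell-type distance drops from 200·4² to
  200·2² + 140·2² log2-units², so both convergence readouts have planted
  headroom before any noise is added.

`simulateAnnotation` places one TSS per gene uniformly on three synthetic
chromosomes with 5 kb clearance from the ends and Bernoulli(0.5) strands.
`simulatePeakLibrary` gives each gene's promoter a peak (width 200 bp,
centered on the TSS) with probability `pFg` for a dataset's target genes
and `pBg` otherwise, plus uniformly placed decoy peaks; planted enrichment
is recorded as truth labels.

One deliberate asymmetry: per-sample `libraryScaleFactors` planted in the
*counts* are removed again by RPKM itself (RPKM divides by the per-sample
total, which is exactly where a depth factor lands), so they cannot be
used to validate the normalization factors. Normalization recovery is
therefore tested with `simulateScaledExpression`, which plants column
scale factors directly in an expression matrix with no gene effects; the
estimated NFs must match the planted factors, up to one global constant,
within 5% relative error per sample at 2000 genes.

What the generator does **not** emulate: mean-dependent dispersion trends,
GC and length biases beyond the length-proportional mean, correlated genes
within programs, batch effects, realistic ChIP-seq signal shapes or
peak-width distributions, and chromosomal clustering of co-regulated
genes. Passing tests therefore demonstrate that the *procedures* are
implemented correctly and are calibrated under their own assumptions, not
that those assumptions hold in any particular real dataset.

# Numerical conventions and degenerate inputs

- All on-disk genomic coordinates are 0-based half-open (BED convention),
  including annotation TSS values; in memory the package uses Bioconductor
  `GRanges` (1-based closed) with the conversion confined to the I/O
  layer. Coordinates survive any number of round-trips exactly.
- Malformed inputs are hard errors, never skipped lines: zero-length BED
  intervals and non-numeric coordinates abort with the line number;
  counts must be non-negative integers; strands must be + or -.
- Ties in expression ranking break lexicographically; all generators and
  the enrichment test are deterministic given a seed, with derived
  per-stream seeds (31-bit rolling hash) for independent substreams.
- Medians over even counts are the mean of the two central order
  statistics, everywhere.

# Problem sizes used in the validation suite

The packaged checks run the worked 2500-gene overlap example exactly; NF
recovery on 2000 genes x 8 samples; the all-pairs overlap oracle on 100
random instances up to 500 regions x 5000 peaks; null calibration over
500 (dataset x input-set) trials at 2000 iterations each; enrichment
recovery over 50 seeded 20-dataset libraries with 2 planted targets; ANOVA
size and BH FDR on 5000 simulated genes; and convergence recovery over 100
seeded replicates of the full pipeline. These sizes keep every stage's
Monte-Carlo error well inside the asserted tolerances.

# Known limitations

- The ANOVA is a fixed-effects Gaussian model on log2 values; it does not
  model count-level mean-variance relationships (no shrinkage or GLM), so
  with n = 2 replicates per condition its per-gene variance estimates are
  noisy — the reason the generator defaults to n = 3.
- The normal approximation behind the enrichment p-value is a
  continuous approximation to a discrete overlap count; for very small
  universes or input sets the calibration band widens, which is why the
  null-calibration check uses an interval around the nominal rate rather
  than an exact match.
- The two shared-percentage conventions can differ materially for very
  unequal set sizes; both are always emitted.
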