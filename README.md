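# StimConverge

Tools for a recurring question in inflammation biology: when two distinct
cell types — say adipocytes and macrophages — are exposed to the same
inflammatory stimuli (IFN-β, LPS, or both), **how far do their
transcriptomes converge**, and **which transcription factors plausibly
drive the genes they induce**? StimConverge is aimed at computational
biologists analyzing bulk RNA-seq stimulation experiments who want the
full chain — quantification, normalization, differential expression,
convergence statistics and promoter–peak enrichment — as tested,
reusable, seed-reproducible functions rather than a one-off script.

## What it computes

**Expression chain.** From gene-level counts:
RPKM = count / ((L/1000)·(N/10⁶)); flooring at 1 RPKM; median-of-ratios
normalization (per-gene geometric mean g across samples, per-sample
NF = medianᵍ(vₛ/g), values divided by NF); per-gene log₂
median-centering ("baselining"); and an expressed-gene filter (raw
RPKM > 3 in 100% of samples of at least one condition).

**Differential expression.** Per-gene fixed-effects two-way ANOVA
(cell type × treatment, with interaction when replication permits),
Benjamini–Hochberg FDR across genes, and per-(cell type, treatment)
linear fold changes versus the untreated baseline; a gene is called when
q < 0.05 and FC > 1.5 (both strict).

**Convergence.** Overlap statistics between the two cell types'
differential sets per condition (both percentage conventions:
100·|A∩B|/|A∪B| and 100·|A∩B|/(|A|+|B|)), top-expressed-gene overlap at
baseline, sample PCA on baselined values, and cross-cell-type centroid
distances per condition.

**Regulatory enrichment.** For a gene set G and each peak dataset D in a
library: strand-aware promoter windows ((−1000,+500), (−1000,+1000),
(−2000,+1) around the TSS), the observed count of windows overlapping D
by ≥ 1 base, an empirical null from 2000 draws of |G| random promoters
(size- and length-matched, without replacement),
Z = (observed − mean)/sd, a one-sided normal p, and BH-adjusted q across
the library — yielding ranked candidate regulators.

**Synthetic data.** A negative-binomial study generator with planted
cell-identity programs, single-stimulus response programs, a dormant
convergence program induced only under the combined treatment, planted
normalization factors, synthetic promoter annotations and peak libraries
with planted enrichment — so every stage has a recoverable ground truth.

## Worked example

```r
library(StimConverge)

cfg <- simulationConfig()              # 2 cell types x 4 treatments, n = 3
cm  <- simulateExpression(cfg, seed = 7)
pr  <- processExpression(cm)           # RPKM -> floor -> NF -> baseline
de  <- differentialExpression(pr$baselined[pr$keptGenes, ], pr$normalized)

conditionOverlapTable(deSets(de))
#>   condition intersection union jaccard_pct
#> 1      IFNB           67   243        27.6
#> 2       LPS           47   245        19.2
#> 3  IFNB_LPS          808  1256        64.3

pca <- pcaSamples(pr$baselined, pr$keptGenes)
centroidDistance(pca, "NS")[["plane"]]        # 56.2
centroidDistance(pca, "IFNB_LPS")[["plane"]]  # 33.1
```

The combined treatment shares 64.3% of differential genes between the two
cell types versus 27.6%/19.2% for the single stimuli, and the
cross-cell-type centroid distance drops from 56.2 to 33.1 — the planted
convergence, recovered. Now rank candidate regulators of the genes
induced by the combined treatment:

```r
anno  <- simulateAnnotation(cfg, seed = 7)
genes <- deSets(de)[["adipocyte.IFNB_LPS"]][1:100]
lib   <- simulatePeakLibrary(anno, 10, enriched = list(ds04 = genes),
                             pFg = 0.8, pBg = 0.1, seed = 7)
res   <- enrichLibrary(genes, anno, lib$datasets,
                       windows = list(promoterWindowDef(1000, 500)),
                       nIter = 2000, seed = 7)
head(as.data.frame(res)[, c("dataset_id", "observed", "null_mean", "z", "p")], 3)
#>   dataset_id observed null_mean          z            p
#> 1       ds04       86   14.7355 20.4544959 2.739282e-93
#> 2       ds05       21   10.9305  3.2758870 5.266535e-04
#> 3       ds03       10    9.6855  0.1101939 4.561278e-01
```

The planted dataset ds04 overlaps 86 of the 100 input promoters against a
null expectation of ~14.7, z ≈ 20 — first by a wide margin.

A command-line wrapper over the same functions
(`inst/scripts/stimconverge.R`) provides `simulate`, `quantify`,
`diffexp`, `converge` and `enrich` subcommands for file-based pipelines.

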