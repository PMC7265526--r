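# Fixtures built in code; no files are stored in the repository.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(S4Vectors)
})

tinyMetadata <- function(sample_ids, cell_type = "adipocyte",
                         treatment = "NS") {
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids,
             cell_type = rep_len(cell_type, n),
             treatment = rep_len(treatment, n),
             replicate = seq_len(n))
}

tinyCounts <- function(counts, lengths,
                       meta = tinyMetadata(colnames(counts))) {
  CountMatrix(counts, lengths, meta)
}

# ExpressionMatrix straight from a value matrix, for unit tests of single
# processing steps.
exprFromMatrix <- function(vals, state = "raw", meta = NULL,
                           normFactors = numeric(0), floor = NA_real_) {
  if (is.null(meta)) meta <- tinyMetadata(colnames(vals))
  if (state %in% c("normalized", "baselined") && !length(normFactors))
    normFactors <- rep(1, ncol(vals))
  cd <- DataFrame(cell_type = meta$cell_type, treatment = meta$treatment,
                  replicate = meta$replicate, row.names = meta$sample_id)
  se <- SummarizedExperiment(assays = list(exprs = vals), colData = cd)
  new("ExpressionMatrix", se, state = state, normFactors = normFactors,
      floor = floor)
}

tinyAnnotation <- function(n = 20, chrom_len = 1e6, seed = 42) {
  withr::with_seed(seed, {
    tss <- sort(sample(seq(10000, chrom_len - 10000, by = 3000), n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
  })
  gr <- GRanges("chr1", IRanges(tss + 1L, width = 1L), strand = strand)
  names(gr) <- sprintf("g%05d", seq_len(n))
  seqlengths(gr) <- c(chr1 = chrom_len)
  gr
}

rangesFromTriplets <- function(chrom, start0, end0) {
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  gr
}

# O(n*m) all-pairs overlap count, written independently of GenomicRanges:
# every region is compared against every peak on raw 0-based half-open
# coordinates (outer products, no interval index).
bruteForceOverlap <- function(reg, pk) {
  if (!length(reg) || !length(pk)) return(0L)
  rc <- as.character(seqnames(reg)); rs <- start(reg) - 1L; re <- end(reg)
  pc <- as.character(seqnames(pk)); ps <- start(pk) - 1L; pe <- end(pk)
  pair <- outer(rc, pc, "==") &
    outer(rs, pe, "<") & outer(re, ps, ">")
  sum(rowSums(pair) > 0L)
}

# Median-of-ratios by a deliberately different code path (explicit sort,
# explicit product-based geometric mean).
bruteForceNF <- function(v) {
  n <- ncol(v)
  keep <- apply(v, 1, function(r) all(r > 0))
  v <- v[keep, , drop = FALSE]
  gm <- apply(v, 1, function(r) prod(r)^(1 / n))
  vapply(seq_len(n), function(s) {
    r <- sort(v[, s] / gm)
    k <- length(r)
    if (k %% 2 == 1) r[(k + 1) / 2] else (r[k / 2] + r[k / 2 + 1]) / 2
  }, numeric(1))
}
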