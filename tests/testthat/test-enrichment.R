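annoAt <- function(tss0, strand, chrom_len = 1e6) {
  gr <- GRanges("chr1", IRanges(tss0 + 1L, width = 1L), strand = strand)
  names(gr) <- sprintf("g%02d", seq_along(tss0))
  seqlengths(gr) <- c(chr1 = chrom_len)
  gr
}

test_that("promoter windows follow the strand-aware coordinate rules", {
  w <- promoterWindowDef(1000, 500)
  # plus strand, TSS 10000 -> [9000, 10500), length 1500
  win <- promoterWindows("g01", annoAt(10000L, "+"), w)
  expect_identical(c(start(win) - 1L, end(win)), c(9000L, 10500L))
  expect_identical(width(win), 1500L)
  # minus strand is the mirror image: [9501, 11001), same length
  win2 <- promoterWindows("g01", annoAt(10000L, "-"), w)
  expect_identical(c(start(win2) - 1L, end(win2)), c(9501L, 11001L))
  expect_identical(width(win2), 1500L)
  # clamping at the chromosome start: TSS 300 with (-2000, +1) -> [0, 301)
  win3 <- promoterWindows("g01", annoAt(300L, "+"),
                          promoterWindowDef(2000, 1))
  expect_identical(c(start(win3) - 1L, end(win3)), c(0L, 301L))
  # clamping at the chromosome end
  win4 <- promoterWindows("g01", annoAt(999900L, "+"),
                          promoterWindowDef(10, 500))
  expect_identical(end(win4), 1000000L)

  expect_error(promoterWindows("missing", annoAt(10000L, "+"), w),
               "absent")
  expect_error(promoterWindowDef(0, 0), "at least one base")
})

test_that("observed overlap counts regions touching any peak once", {
  reg <- rangesFromTriplets("chr1", c(100L, 1000L), c(200L, 1100L))
  expect_identical(observedOverlap(reg, GRanges()), 0L)
  # single shared base 199
  pk <- rangesFromTriplets("chr1", 199L, 300L)
  expect_identical(observedOverlap(reg, pk), 1L)
  # half-open: [0,10) and [10,20) do not overlap, [9,20) does
  r0 <- rangesFromTriplets("chr1", 0L, 10L)
  expect_identical(observedOverlap(r0, rangesFromTriplets("chr1", 10L,
                                                          20L)), 0L)
  expect_identical(observedOverlap(r0, rangesFromTriplets("chr1", 9L,
                                                          20L)), 1L)
  # a region covered by many peaks counts once
  many <- rangesFromTriplets("chr1", c(100L, 120L, 140L),
                             c(130L, 150L, 210L))
  expect_identical(observedOverlap(reg, many), 1L)
})

test_that("observed overlap equals the all-pairs brute force", {
  set.seed(31)
  for (i in 1:25) {
    nr <- sample(5:60, 1); np <- sample(5:300, 1)
    rs <- sample(0:50000, nr)
    ps <- sample(0:50000, np)
    reg <- rangesFromTriplets(sample(c("chr1", "chr2"), nr, TRUE),
                              rs, rs + sample(1:800, nr, TRUE))
    pk <- rangesFromTriplets(sample(c("chr1", "chr2"), np, TRUE),
                             ps, ps + sample(1:400, np, TRUE))
    expect_identical(observedOverlap(reg, pk), bruteForceOverlap(reg, pk))
  }
})

test_that("strand flips with mirrored peaks preserve every overlap", {
  set.seed(44)
  n <- 80
  # TSS spaced >= 9 kb apart so each window can only meet its own peak
  tss0 <- seq(20000, by = 10000, length.out = n) +
    sample(-500:500, n, TRUE)
  str <- sample(c("+", "-"), n, TRUE)
  anno <- annoAt(as.integer(tss0), str)
  # peaks placed at a random offset from each TSS
  off <- sample(-1500:1500, n, TRUE)
  s0 <- as.integer(tss0 + off)
  pk <- rangesFromTriplets("chr1", s0, s0 + 120L)
  # mirrored experiment: strands flipped, peaks reflected about each TSS
  anno_m <- annoAt(as.integer(tss0), ifelse(str == "+", "-", "+"))
  e0 <- s0 + 120L
  s0m <- as.integer(2L * tss0 - e0 + 1L)
  pk_m <- rangesFromTriplets("chr1", s0m, s0m + 120L)
  for (w in standardWindowDefs()) {
    win <- promoterWindows(names(anno), anno, w)
    win_m <- promoterWindows(names(anno_m), anno_m, w)
    # per-gene hit indicators are identical, not just the totals
    expect_identical(overlapsAny(win, pk), overlapsAny(win_m, pk_m))
  }
})

test_that("the resampled null matches forced and binomial regimes", {
  anno <- tinyAnnotation(200, chrom_len = 5e6)
  w <- promoterWindowDef(1000, 500)
  universe <- promoterWindows(names(anno), anno, w)

  # peaks covering every promoter: every draw overlaps everything
  all_pk <- universe
  nd <- sampleNull(20, universe, all_pk, nIter = 50, seed = 2)
  expect_true(all(nullSamples(nd) == 20L))
  # no peaks at all: all zero, sd 0
  nd0 <- sampleNull(20, universe, GRanges(), nIter = 50, seed = 2)
  expect_true(all(nullSamples(nd0) == 0L) && nullSd(nd0) == 0)

  # exactly 10% of promoters carry a peak: the null mean of a 50-promoter
  # draw is 5 (hypergeometric), within 3 standard errors at 2000 draws
  hit <- universe[seq_len(20)]
  nd1 <- sampleNull(50, universe, hit, nIter = 2000, seed = 3)
  se <- stats::sd(nullSamples(nd1)) / sqrt(2000)
  expect_lt(abs(nullMean(nd1) - 5), 3 * se + 1e-9)
  expect_identical(nd1@nIter, 2000L)

  expect_error(sampleNull(300, universe, hit), "exceeds")
  # determinism
  nd2 <- sampleNull(50, universe, hit, nIter = 100, seed = 9)
  nd3 <- sampleNull(50, universe, hit, nIter = 100, seed = 9)
  expect_identical(nullSamples(nd2), nullSamples(nd3))
})

test_that("Z and P follow the declared normal-tail conventions", {
  # samples (8, 10, 12): mean 10, sd exactly 2 (n-1 denominator)
  nd <- new("NullDistribution", samples = c(8L, 10L, 12L), nIter = 3L,
            nullMean = 10, nullSd = 2, seed = 1L)
  expect_equal(zPFromNull(10, nd)$z, 0)
  expect_equal(zPFromNull(10, nd)$p, 0.5)
  zp <- zPFromNull(16, nd)
  expect_equal(zp$z, 3)
  expect_equal(zp$p, pnorm(3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(zp$p, 1.349898e-3, tolerance = 1e-6)
  expect_equal(zPFromNull(16, nd, tail = "two")$p,
               2 * pnorm(3, lower.tail = FALSE), tolerance = 1e-12)

  # p is strictly decreasing in the observed count
  ps <- vapply(5:15, function(o) zPFromNull(o, nd)$p, numeric(1))
  expect_true(all(diff(ps) < 0))

  # degenerate null
  nd0 <- new("NullDistribution", samples = rep(4L, 5), nIter = 5L,
             nullMean = 4, nullSd = 0, seed = 1L)
  expect_equal(zPFromNull(4, nd0), list(z = 0, p = 0.5,
                                        degenerate = TRUE))
  up <- zPFromNull(9, nd0)
  expect_identical(up$z, Inf)
  expect_lte(up$p, 1e-300)
  down <- zPFromNull(2, nd0)
  expect_identical(down$z, -Inf)
  expect_identical(down$p, 1)

  # the class itself refuses inconsistent summaries
  expect_error(new("NullDistribution", samples = c(1L, 2L), nIter = 2L,
                   nullMean = 5, nullSd = 1, seed = 1L), "inconsistent")
})

test_that("library enrichment ranks planted datasets first", {
  anno <- simulateAnnotation(simulationConfig(), seed = 3)[1:400]
  genes <- names(anno)[21:80]
  lib <- simulatePeakLibrary(anno, 8,
                             enriched = list(ds02 = genes, ds06 = genes),
                             pFg = 0.8, pBg = 0.1, seed = 6)
  res <- enrichLibrary(genes, anno, lib$datasets,
                       windows = list(promoterWindowDef(1000, 500)),
                       nIter = 500, seed = 10)
  df <- as.data.frame(res)
  expect_setequal(df$dataset_id[1:2], c("ds02", "ds06"))
  # z sorted descending, q is BH of p within the window
  expect_true(all(diff(df$z) <= 0))
  expect_equal(df$q, bhAdjust(df$p), tolerance = 1e-12)

  # identical master seed reproduces the full table
  res2 <- enrichLibrary(genes, anno, lib$datasets,
                        windows = list(promoterWindowDef(1000, 500)),
                        nIter = 500, seed = 10)
  expect_identical(as.data.frame(res2), df)

  # a single-dataset library has q = p
  res1 <- enrichLibrary(genes, anno, lib$datasets["ds02"],
                        windows = list(promoterWindowDef(1000, 500)),
                        nIter = 200, seed = 10)
  expect_identical(res1$q, res1$p)
})

test_that("enrichment sign agrees across the promoter definitions", {
  anno <- simulateAnnotation(simulationConfig(), seed = 23)[1:500]
  genes <- names(anno)[1:80]
  lib <- simulatePeakLibrary(anno, 10,
                             enriched = setNames(
                               rep(list(genes), 3),
                               c("ds01", "ds05", "ds09")),
                             pFg = 0.7, pBg = 0.05, seed = 31)
  res <- as.data.frame(enrichLibrary(genes, anno, lib$datasets,
                                     nIter = 300, seed = 12))
  sgn <- tapply(sign(res$z), res$dataset_id,
                function(s) length(unique(s[s != 0])))
  # promoter-centered peaks: the direction of the effect is window-robust
  expect_gte(mean(sgn <= 1), 0.9)
})
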