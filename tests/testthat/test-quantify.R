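test_that("RPKM follows its unit definition", {
  # one sample totalling 1e6 reads: count 10 on a 1 kb gene -> RPKM 10;
  # plus the hand-evaluated 300/1.5kb and 200/0.5kb cases
  cts <- matrix(c(10L, 300L, 200L, 999490L), 4,
                dimnames = list(c("g1", "g2", "g3", "filler"), "s1"))
  cm <- tinyCounts(cts, c(1000, 1500, 500, 1e6))
  r <- exprValues(computeRpkm(cm))
  expect_equal(unname(r[1:3, 1]), c(10, 200, 400))
  expect_identical(exprState(computeRpkm(cm)), "raw")

  cts0 <- matrix(c(0L, 10L, 5L, 5L), 2,
                 dimnames = list(c("g1", "g2"), c("a", "b")))
  cm0 <- tinyCounts(cts0, c(2000, 2000))
  expect_equal(unname(exprValues(computeRpkm(cm0))["g1", "a"]), 0)

  czero <- matrix(c(1L, 0L), 1, dimnames = list("g1", c("a", "b")))
  expect_error(computeRpkm(tinyCounts(czero, 1000)), "zero total")
})

test_that("thresholding floors values and is idempotent", {
  v <- matrix(c(0.2, 5, 1, 0.99), 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  m <- exprFromMatrix(v)
  t1 <- thresholdRpkm(m)
  expect_equal(unname(exprValues(t1)), matrix(c(1, 5, 1, 1), 2))
  expect_identical(exprState(t1), "thresholded")
  expect_error(thresholdRpkm(t1), "raw")

  set.seed(1)
  r <- exprFromMatrix(matrix(rexp(200, 1), 20,
                             dimnames = list(sprintf("g%02d", 1:20),
                                             sprintf("s%d", 1:10))))
  once <- exprValues(thresholdRpkm(r))
  again <- pmax(once, 1)
  expect_identical(once, again)
})

test_that("normalization factors implement median-of-ratios", {
  # identical samples are already comparable
  v <- matrix(c(2, 8, 5, 2, 8, 5), 3,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  expect_equal(unname(computeNormFactors(exprFromMatrix(v, "thresholded"))),
               c(1, 1))

  # sample b = 2 * sample a: per-gene geometric mean is a*sqrt(2), so the
  # ratio medians are 1/sqrt(2) and sqrt(2)
  v2 <- cbind(a = c(2, 8, 5), b = c(4, 16, 10))
  rownames(v2) <- c("g1", "g2", "g3")
  nf <- computeNormFactors(exprFromMatrix(v2, "thresholded"))
  expect_equal(unname(nf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # random positive matrices agree with an independently coded oracle
  set.seed(11)
  for (dims in list(c(21, 4), c(30, 5), c(16, 6))) {
    v3 <- matrix(rexp(prod(dims), 0.2) + 0.5, dims[1],
                 dimnames = list(sprintf("g%02d", seq_len(dims[1])),
                                 sprintf("s%d", seq_len(dims[2]))))
    expect_equal(unname(computeNormFactors(exprFromMatrix(v3,
                                                          "thresholded"))),
                 bruteForceNF(v3), tolerance = 1e-12)
  }
})

test_that("normalization factors match the reference median-of-ratios code", {
  skip_if_not_installed("DESeq2")
  set.seed(3)
  # odd gene count: ratio-scale and log-scale medians then coincide
  v <- matrix(rpois(606, 50) + 1, 101,
              dimnames = list(sprintf("g%03d", 1:101), sprintf("s%d", 1:6)))
  nf <- computeNormFactors(exprFromMatrix(v * 1.0, "thresholded"))
  ref <- DESeq2::estimateSizeFactorsForMatrix(v)
  expect_equal(unname(nf), unname(ref), tolerance = 1e-8)
})

test_that("applying normalization rescales samples as specified", {
  v2 <- cbind(a = c(2, 8, 5), b = c(4, 16, 10))
  rownames(v2) <- c("g1", "g2", "g3")
  m <- exprFromMatrix(v2, "thresholded")
  norm <- applyNormalization(m)
  # after dividing by the NFs the doubled sample equals the original
  expect_equal(exprValues(norm)[, "a"], exprValues(norm)[, "b"])
  expect_identical(exprState(norm), "normalized")
  expect_equal(unname(normFactors(norm)), c(1 / sqrt(2), sqrt(2)))

  ident <- applyNormalization(m, nf = c(1, 1))
  expect_equal(exprValues(ident), exprValues(m))
  expect_error(applyNormalization(m, nf = c(1, 1, 1)), "per sample")
})

test_that("scaling one sample scales its relative NF exactly", {
  set.seed(8)
  v <- matrix(rexp(120, 0.1) + 1, 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:4)))
  nf <- computeNormFactors(exprFromMatrix(v, "thresholded"))
  for (c_fac in c(0.5, 3)) {
    v2 <- v
    v2[, 2] <- v2[, 2] * c_fac
    nf2 <- computeNormFactors(exprFromMatrix(v2, "thresholded"))
    # all-positive, no-threshold regime: the NF ratio moves by exactly c
    expect_equal(nf2[2] / nf2[1], c_fac * nf[2] / nf[1], tolerance = 1e-10)
  }
})

test_that("baselining centers log2 values at the per-gene median", {
  v <- rbind(g1 = c(4, 4, 4), g2 = c(2, 8, 4))
  colnames(v) <- c("a", "b", "c")
  m <- exprFromMatrix(v, "normalized", normFactors = c(1, 1, 1))
  b <- baselineToMedian(m)
  expect_equal(unname(exprValues(b)["g1", ]), c(0, 0, 0))
  expect_identical(exprState(b), "baselined")

  # two samples at 2 and 8: log2 = 1 and 3, median 2 -> (-1, +1)
  v2 <- rbind(g1 = c(2, 8))
  colnames(v2) <- c("a", "b")
  b2 <- baselineToMedian(exprFromMatrix(v2, "normalized",
                                        normFactors = c(1, 1)))
  expect_equal(unname(exprValues(b2)["g1", ]), c(-1, 1))

  # odd sample count: the per-gene median of baselined values is 0
  set.seed(2)
  v3 <- matrix(rexp(50 * 5, 0.2) + 1, 50,
               dimnames = list(sprintf("g%02d", 1:50),
                               sprintf("s%d", 1:5)))
  b3 <- baselineToMedian(exprFromMatrix(v3, "normalized",
                                        normFactors = rep(1, 5)))
  expect_equal(unname(apply(exprValues(b3), 1, median)), rep(0, 50))

  vb <- rbind(g1 = c(0, 2))
  colnames(vb) <- c("a", "b")
  bad <- exprFromMatrix(vb, "normalized", normFactors = c(1, 1))
  expect_error(baselineToMedian(bad), "positive")
})

test_that("the expressed-gene filter requires a fully passing condition", {
  meta <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                     cell_type = "adipocyte",
                     treatment = rep(c("NS", "LPS"), each = 2),
                     replicate = c(1, 2, 1, 2))
  v <- rbind(g_in = c(3.5, 4.1, 0, 0),      # passes in NS
             g_partial = c(3.5, 2.9, 3.5, 2.9), # never 100% of a condition
             g_boundary = c(3, 3, 3, 3))    # exactly the cutoff: strict >
  colnames(v) <- meta$sample_id
  m <- exprFromMatrix(v, meta = meta)
  expect_identical(expressionFilter(m, cutoff = 3), "g_in")

  # raising the cutoff never enlarges the retained set
  set.seed(5)
  v2 <- matrix(rexp(80 * 4, 0.2), 80,
               dimnames = list(sprintf("g%02d", 1:80), meta$sample_id))
  m2 <- exprFromMatrix(v2, meta = meta)
  kept <- lapply(c(1, 2, 3, 5), function(ct) expressionFilter(m2, ct))
  for (i in 2:4) expect_true(all(kept[[i]] %in% kept[[i - 1]]))
})

test_that("the processing chain is deterministic and state-ordered", {
  cfg <- simulationConfig(nGenes = 80L, nReplicates = 2L,
                          nIdentityGenes = 5L,
                          nSharedResponseGenes = c(IFNB = 4L, LPS = 4L),
                          nPrivateResponseGenes = c(IFNB = 4L, LPS = 4L),
                          nDormantGenes = 8L)
  cm <- simulateExpression(cfg, seed = 31)
  p1 <- processExpression(cm)
  p2 <- processExpression(cm)
  expect_identical(exprValues(p1$baselined), exprValues(p2$baselined))
  expect_identical(p1$nf, p2$nf)
  expect_identical(p1$keptGenes, p2$keptGenes)
  # state transitions occur in the documented order
  expect_identical(vapply(p1[c("raw", "thresholded", "normalized",
                               "baselined")], exprState, character(1)),
                   c(raw = "raw", thresholded = "thresholded",
                     normalized = "normalized", baselined = "baselined"))
  # and out-of-order transitions are refused
  expect_error(baselineToMedian(p1$thresholded), "normalized")
  expect_error(thresholdRpkm(p1$normalized), "raw")
})
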