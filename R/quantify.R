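#' @importFrom stats median
NULL

#' Compute RPKM from gene-level counts
#'
#' \code{rpkm = count / ((length/1000) * (total/1e6))} where \code{total}
#' is the sample's summed counts.
#'
#' @param x a \linkS4class{CountMatrix}.
#' @return An \linkS4class{ExpressionMatrix} at state \code{"raw"}.
#' @export
computeRpkm <- function(x) {
  stopifnot(is(x, "CountMatrix"))
  cts <- counts(x)
  totals <- colSums(cts)
  if (any(totals == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(cts)[totals == 0], collapse = ", "))
  len_kb <- rowData(x)$length_bp / 1000
  vals <- sweep(cts / len_kb, 2, totals / 1e6, "/")
  .newExpressionMatrix(vals, x, "raw")
}

#' Floor an RPKM matrix
#'
#' Values below \code{floor} are replaced by \code{floor}; idempotent.
#'
#' @param m an \linkS4class{ExpressionMatrix} at state \code{"raw"}.
#' @param floor flooring value (default 1).
#' @return The matrix at state \code{"thresholded"}.
#' @export
thresholdRpkm <- function(m, floor = 1) {
  if (exprState(m) != "raw")
    stop("thresholding applies to state 'raw', got '", exprState(m), "'")
  .newExpressionMatrix(pmax(exprValues(m), floor), m, "thresholded",
                       floor = floor)
}

#' Median-of-ratios normalization factors
#'
#' Each gene's values are divided by that gene's geometric mean across
#' samples; a sample's normalization factor (NF) is the within-sample
#' median of these ratios. Genes with a zero in any sample are excluded
#' (after flooring at 1 none remain). With an even number of eligible
#' genes the median is the mean of the two central order statistics.
#'
#' @param m an \linkS4class{ExpressionMatrix} at state \code{"thresholded"}
#'   (or \code{"raw"} when thresholding is deliberately skipped).
#' @return named numeric vector of per-sample NFs.
#' @export
computeNormFactors <- function(m) {
  if (!exprState(m) %in% c("raw", "thresholded"))
    stop("normalization factors are computed before normalization")
  v <- exprValues(m)
  if (ncol(v) < 2) stop("need at least two samples")
  ok <- rowSums(v == 0) == 0
  if (!any(ok))
    stop("no gene is positive in all samples; cannot form geometric means")
  v <- v[ok, , drop = FALSE]
  gm <- exp(rowMeans(log(v)))
  nf <- apply(v / gm, 2, median)
  setNames(nf, colnames(v))
}

#' Apply normalization factors
#'
#' Each sample's values are divided by that sample's NF.
#'
#' @param m an \linkS4class{ExpressionMatrix} at state \code{"thresholded"}
#'   (or \code{"raw"}).
#' @param nf per-sample normalization factors, defaulting to
#'   \code{computeNormFactors(m)}.
#' @return The matrix at state \code{"normalized"}, with the factors
#'   retrievable via \code{\link{normFactors}}.
#' @export
applyNormalization <- function(m, nf = computeNormFactors(m)) {
  if (!exprState(m) %in% c("raw", "thresholded"))
    stop("normalization applies before baselining")
  if (length(nf) != ncol(m))
    stop("need one normalization factor per sample (", ncol(m), ")")
  if (any(nf <= 0)) stop("normalization factors must be positive")
  vals <- sweep(exprValues(m), 2, nf, "/")
  .newExpressionMatrix(vals, m, "normalized", normFactors = unname(nf),
                       floor = m@floor)
}

#' Baseline to the per-gene median
#'
#' Values are log2-transformed, then each gene's median across all samples
#' is subtracted, so every gene is centered at zero (exactly zero median
#' for odd sample counts).
#'
#' @param m an \linkS4class{ExpressionMatrix} at state \code{"normalized"}.
#' @return The matrix at state \code{"baselined"} (log2 units).
#' @export
baselineToMedian <- function(m) {
  if (exprState(m) != "normalized")
    stop("baselining applies to state 'normalized', got '",
         exprState(m), "'")
  v <- exprValues(m)
  if (any(v <= 0))
    stop("baselining requires strictly positive normalized values")
  lv <- log2(v)
  lv <- lv - apply(lv, 1, median)
  .newExpressionMatrix(lv, m, "baselined", normFactors = m@normFactors,
                       floor = m@floor)
}

#' Expressed-gene filter
#'
#' A gene is retained if there is at least one (cell type, treatment)
#' condition in which \emph{every} sample's raw RPKM is strictly greater
#' than \code{cutoff}.
#'
#' @param raw an \linkS4class{ExpressionMatrix} at state \code{"raw"}
#'   (the filter operates on raw, pre-normalization RPKM).
#' @param cutoff expression cutoff (default 3).
#' @return character vector of retained gene ids.
#' @export
expressionFilter <- function(raw, cutoff = 3) {
  if (exprState(raw) != "raw")
    stop("the expression filter uses raw RPKM")
  cd <- colData(raw)
  if (any(is.na(cd$cell_type)) || any(is.na(cd$treatment)))
    stop("every sample must be assigned to a (cell_type, treatment) ",
         "condition")
  cond <- paste(cd$cell_type, cd$treatment, sep = ".")
  v <- exprValues(raw)
  keep <- Reduce(`|`, lapply(split(seq_len(ncol(v)), cond), function(j)
    rowSums(v[, j, drop = FALSE] > cutoff) == length(j)))
  rownames(v)[keep]
}

#' Run the full expression-processing chain
#'
#' Convenience wrapper: RPKM, flooring, normalization factors,
#' normalization, per-gene median baselining, and the expressed-gene
#' filter.
#'
#' @param x a \linkS4class{CountMatrix}.
#' @param floor RPKM flooring value (default 1); \code{NULL} skips
#'   thresholding.
#' @param filterCutoff raw-RPKM cutoff of the expressed-gene filter.
#' @return list with elements \code{raw}, \code{thresholded},
#'   \code{normalized}, \code{baselined} (all
#'   \linkS4class{ExpressionMatrix}), \code{nf} and \code{keptGenes}.
#' @export
processExpression <- function(x, floor = 1, filterCutoff = 3) {
  raw <- computeRpkm(x)
  thr <- if (is.null(floor)) raw else thresholdRpkm(raw, floor)
  nf <- computeNormFactors(thr)
  norm <- applyNormalization(thr, nf)
  base <- baselineToMedian(norm)
  list(raw = raw, thresholded = thr, normalized = norm, baselined = base,
       nf = nf, keptGenes = expressionFilter(raw, filterCutoff))
}
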