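#' @importFrom stats prcomp
NULL

#' Top expressed genes for a cell type
#'
#' Genes ranked by mean normalized RPKM over the given cell type's samples
#' in one condition (descending); ties broken by lexicographic gene id so
#' the ranking is deterministic.
#'
#' @param m an \linkS4class{ExpressionMatrix} at state \code{"normalized"}.
#' @param cellType cell-type label.
#' @param condition treatment label (default \code{"NS"}, the untreated
#'   baseline).
#' @param n number of genes to return (default 2500).
#' @return character vector of the top \code{n} gene ids, in rank order.
#' @export
topExpressed <- function(m, cellType, condition = "NS", n = 2500) {
  if (exprState(m) != "normalized")
    stop("ranking uses normalized expression values")
  cd <- colData(m)
  j <- which(cd$cell_type == cellType & cd$treatment == condition)
  if (!length(j))
    stop("no samples for (", cellType, ", ", condition, ")")
  if (n > nrow(m))
    stop("n exceeds the number of genes (", nrow(m), ")")
  mu <- rowMeans(exprValues(m)[, j, drop = FALSE])
  ids <- rownames(m)
  ids[order(-mu, ids)][seq_len(n)]
}

#' Overlap statistics between two gene sets
#'
#' Returns set sizes, intersection and union, and the shared-gene
#' percentages under two conventions: \code{jaccard_pct} =
#' 100 * |A&B| / |A|B union| and \code{sum_pct} = 100 * |A&B| / (|A|+|B|),
#' plus the percentage of each set covered by the intersection.
#' Percentages are kept at full precision; round only when reporting.
#'
#' @param a,b character vectors of gene ids (duplicates ignored).
#' @return one-row data.frame with columns \code{size_a}, \code{size_b},
#'   \code{intersection}, \code{union}, \code{jaccard_pct},
#'   \code{sum_pct}, \code{frac_of_a_pct}, \code{frac_of_b_pct}.
#' @export
overlapStats <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b))
    stop("both sets are empty; overlap percentages are undefined")
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  data.frame(
    size_a = length(a), size_b = length(b),
    intersection = i, union = u,
    jaccard_pct = 100 * i / u,
    sum_pct = 100 * i / (length(a) + length(b)),
    frac_of_a_pct = if (length(a)) 100 * i / length(a) else NA_real_,
    frac_of_b_pct = if (length(b)) 100 * i / length(b) else NA_real_
  )
}

#' Per-condition cross-cell-type overlap table
#'
#' For every treatment, the overlap statistics between the two cell types'
#' differential gene sets; optionally preceded by a baseline row comparing
#' the two cell types' top-expressed sets. Conditions whose union is empty
#' are omitted (their percentages are undefined).
#'
#' @param sets named list of differential gene sets as returned by
#'   \code{\link{deSets}} (elements carry \code{cell_type} and
#'   \code{treatment} attributes).
#' @param baselineSets optional list of two top-expressed gene vectors
#'   (one per cell type) for a \code{"baseline"} row.
#' @return data.frame, one row per condition, columns \code{condition} plus
#'   the \code{\link{overlapStats}} fields.
#' @export
conditionOverlapTable <- function(sets, baselineSets = NULL) {
  ct <- vapply(sets, attr, character(1), "cell_type")
  trt <- vapply(sets, attr, character(1), "treatment")
  cts <- unique(ct)
  if (length(cts) != 2)
    stop("expected differential sets for exactly two cell types")
  rows <- list()
  if (!is.null(baselineSets)) {
    if (length(baselineSets) != 2)
      stop("baselineSets must hold one gene set per cell type")
    rows$baseline <- cbind(condition = "baseline",
                           overlapStats(baselineSets[[1]],
                                        baselineSets[[2]]))
  }
  for (tr in unique(trt)) {
    ia <- which(ct == cts[1] & trt == tr)
    ib <- which(ct == cts[2] & trt == tr)
    if (!length(ia) || !length(ib))
      stop("treatment '", tr, "' lacks a set for one cell type")
    a <- sets[[ia]]; b <- sets[[ib]]
    if (!length(a) && !length(b)) next
    rows[[tr]] <- cbind(condition = tr, overlapStats(a, b))
  }
  if (!length(rows)) stop("no condition has a non-empty union")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combined-versus-single-treatment overlap within one cell type
#'
#' Overlap statistics between the combined-treatment differential set and
#' each single-treatment set of the same cell type, with the combined set
#' as set A (so \code{frac_of_a_pct} is the fraction of the combined set
#' shared with the single treatment).
#'
#' @param combined character vector: combined-treatment differential set.
#' @param singles named list of single-treatment differential sets.
#' @return data.frame, one row per single treatment.
#' @export
withinCellTypeOverlap <- function(combined, singles) {
  if (!length(combined))
    stop("the combined-treatment set is empty")
  rows <- lapply(names(singles), function(tr)
    cbind(versus = tr, overlapStats(combined, singles[[tr]])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Principal component analysis of samples
#'
#' Samples are projected onto the eigenvectors of the gene-centered
#' covariance (no scaling; baselined values are already per-gene
#' centered). Components are ordered by explained variance, and each
#' component's sign is fixed so that its largest-magnitude gene loading is
#' positive.
#'
#' @param m an \linkS4class{ExpressionMatrix} at state \code{"baselined"}.
#' @param genes optional gene subset (defaults to all genes in \code{m}).
#' @return list with \code{coords} (samples x components score matrix),
#'   \code{rotation} (gene loadings), \code{varExplained} (fractions
#'   summing to 1 over the retained components) and \code{design} (the
#'   sample annotations, for downstream grouping).
#' @export
pcaSamples <- function(m, genes = NULL) {
  if (exprState(m) != "baselined")
    stop("PCA operates on baselined log2 values")
  v <- exprValues(m)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss))
      stop("gene(s) absent from the matrix: ",
           paste(utils::head(miss, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (ncol(v) < 2) stop("PCA needs at least two samples")
  pc <- prcomp(t(v), center = TRUE, scale. = FALSE)
  keep <- pc$sdev > max(pc$sdev) * 1e-8
  if (sum(keep) < 2)
    stop("fewer than two non-degenerate dimensions")
  rot <- pc$rotation[, keep, drop = FALSE]
  coords <- pc$x[, keep, drop = FALSE]
  for (k in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, k])), k] < 0) {
      rot[, k] <- -rot[, k]
      coords[, k] <- -coords[, k]
    }
  }
  list(coords = coords, rotation = rot,
       varExplained = pc$sdev[keep]^2 / sum(pc$sdev^2),
       design = as.data.frame(colData(m)))
}

#' Cross-cell-type centroid distance within a condition
#'
#' Euclidean distance between the two cell types' centroids in PCA space,
#' reported on one designated component alone and on the top-2 component
#' plane.
#'
#' @param pca result of \code{\link{pcaSamples}}.
#' @param condition treatment label selecting the samples.
#' @param component the designated component (default 2, the axis that
#'   separates cell types once treatment dominates component 1).
#' @return named numeric: \code{component} and \code{plane} distances.
#' @export
centroidDistance <- function(pca, condition, component = 2) {
  design <- pca$design
  sel <- design$treatment == condition
  if (!any(sel)) stop("no samples in condition '", condition, "'")
  cts <- unique(design$cell_type[sel])
  if (length(cts) != 2)
    stop("condition '", condition, "' lacks samples for both cell types")
  cen <- vapply(cts, function(k)
    colMeans(pca$coords[sel & design$cell_type == k, , drop = FALSE]),
    numeric(ncol(pca$coords)))
  d <- cen[, 1] - cen[, 2]
  c(component = unname(abs(d[component])),
    plane = sqrt(sum(d[seq_len(min(2, length(d)))]^2)))
}
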