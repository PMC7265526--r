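#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
NULL

.EXPR_STATES <- c("raw", "thresholded", "normalized", "baselined")

#' Gene-level count container
#'
#' A \linkS4class{SummarizedExperiment} holding raw gene-level counts, with
#' gene lengths in \code{rowData(x)$length_bp} and the study design
#' (\code{cell_type}, \code{treatment}, \code{replicate}) in \code{colData}.
#'
#' @slot truth list; optional planted ground-truth labels attached by the
#'   synthetic-data generator (program membership, true scale factors).
#' @export
setClass("CountMatrix",
  contains = "SummarizedExperiment",
  slots = c(truth = "list")
)

setValidity("CountMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(is.na(cts)) || any(cts < 0))
      msg <- c(msg, "counts must be non-negative and non-missing")
    if (any(cts != round(cts)))
      msg <- c(msg, "counts must be integer-valued")
  }
  if (!"length_bp" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'length_bp'")
  else if (any(rowData(object)$length_bp <= 0))
    msg <- c(msg, "gene lengths must be positive")
  need <- c("cell_type", "treatment", "replicate")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData is missing: ", paste(miss, collapse = ", ")))
  else {
    key <- paste(colData(object)$cell_type, colData(object)$treatment,
                 colData(object)$replicate)
    if (anyDuplicated(key))
      msg <- c(msg, "(cell_type, treatment, replicate) must be unique")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' Expression matrix with a processing state
#'
#' A \linkS4class{SummarizedExperiment} whose single assay holds per-gene
#' per-sample expression (RPKM units). The \code{state} slot records the
#' position in the processing chain raw -> thresholded -> normalized ->
#' baselined; transitions are only permitted in that order. Normalization
#' factors appear once the state reaches \code{"normalized"}; baselined
#' values are log2 and median-centered per gene.
#'
#' @slot state character(1); one of raw, thresholded, normalized, baselined.
#' @slot normFactors numeric; per-sample normalization factors (empty before
#'   normalization).
#' @slot floor numeric(1); flooring value applied at thresholding (NA before).
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  slots = c(state = "character", normFactors = "numeric", floor = "numeric")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@state) != 1L || !object@state %in% .EXPR_STATES)
    msg <- c(msg, paste0("state must be one of: ",
                         paste(.EXPR_STATES, collapse = ", ")))
  v <- assay(object)
  if (any(is.na(v)))
    msg <- c(msg, "expression values must not be missing")
  st <- object@state
  if (st %in% c("raw", "thresholded", "normalized") && any(v < 0))
    msg <- c(msg, "pre-baselining expression values must be non-negative")
  if (identical(st, "thresholded") && !is.na(object@floor) &&
      length(v) && min(v) < object@floor)
    msg <- c(msg, "thresholded values must be >= the floor")
  if (st %in% c("normalized", "baselined")) {
    if (length(object@normFactors) != ncol(object))
      msg <- c(msg, "normFactors must have one entry per sample")
    else if (any(object@normFactors <= 0))
      msg <- c(msg, "normalization factors must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Empirical null distribution of overlap counts
#'
#' Holds the expected-overlap values obtained by repeatedly redrawing
#' size-matched random promoter sets, plus their summary statistics.
#' The standard deviation uses the n-1 denominator.
#'
#' @slot samples integer vector of resampled overlap counts.
#' @slot nIter integer(1); number of resampling iterations.
#' @slot nullMean,nullSd numeric(1); mean and sd of \code{samples}.
#' @slot seed integer(1); RNG seed that produced the draws.
#' @export
setClass("NullDistribution",
  slots = c(samples = "integer", nIter = "integer",
            nullMean = "numeric", nullSd = "numeric", seed = "integer")
)

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (length(object@samples) != object@nIter)
    msg <- c(msg, "length(samples) must equal nIter")
  if (any(object@samples < 0))
    msg <- c(msg, "overlap counts must be non-negative")
  if (!isTRUE(all.equal(object@nullMean, mean(object@samples))))
    msg <- c(msg, "nullMean inconsistent with samples")
  sd_ref <- stats::sd(object@samples)
  if (!isTRUE(all.equal(object@nullSd, sd_ref)))
    msg <- c(msg, "nullSd inconsistent with samples (n-1 denominator)")
  if (length(msg)) msg else TRUE
})

#' Per-gene differential-expression results
#'
#' A \linkS4class{DFrame} with one row per gene: per-term F statistics and
#' p-values from the two-way ANOVA, the omnibus p-value used for FDR
#' control, its BH-adjusted q, per-(cell type, treatment) linear fold
#' changes versus the untreated baseline with direction signs, and boolean
#' differential calls. Thresholds and the omnibus convention are stored in
#' \code{metadata()}.
#' @export
setClass("DEResult", contains = "DFrame")

#' Peak-dataset enrichment results
#'
#' A \linkS4class{DFrame} with one row per (peak dataset, promoter window)
#' pair: observed overlap, empirical-null mean/sd, Z-score, one-sided
#' p-value and BH-adjusted q across the dataset library within each window.
#' @export
setClass("EnrichmentResult", contains = "DFrame")

#' @describeIn CountMatrix construct from a count matrix, gene lengths and a
#'   sample-metadata table.
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param lengths positive numeric vector of gene lengths in bp, one per row
#'   of \code{counts}.
#' @param metadata data.frame with columns \code{sample_id},
#'   \code{cell_type}, \code{treatment}, \code{replicate} covering every
#'   column of \code{counts}.
#' @param truth optional list of planted ground-truth labels.
#' @return A validated \code{CountMatrix}.
#' @export
CountMatrix <- function(counts, lengths, metadata, truth = list()) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || is.null(rownames(counts)))
    stop("counts must have row (gene) and column (sample) names")
  missing_meta <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing_meta))
    stop("no metadata for sample column(s): ",
         paste(missing_meta, collapse = ", "))
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                       drop = FALSE]
  cd <- DataFrame(cell_type = as.character(metadata$cell_type),
                  treatment = as.character(metadata$treatment),
                  replicate = as.integer(metadata$replicate),
                  row.names = colnames(counts))
  rd <- DataFrame(length_bp = as.numeric(lengths),
                  row.names = rownames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowData = rd, colData = cd)
  new("CountMatrix", se, truth = truth)
}

.newExpressionMatrix <- function(values, template, state,
                                 normFactors = numeric(0), floor = NA_real_) {
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    rowData = rowData(template),
    colData = colData(template)
  )
  new("ExpressionMatrix", se, state = state, normFactors = normFactors,
      floor = floor)
}
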