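#' @importFrom BiocGenerics counts
NULL

#' Processing state of an expression matrix
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return character(1), one of \code{"raw"}, \code{"thresholded"},
#'   \code{"normalized"}, \code{"baselined"}.
#' @export
setGeneric("exprState", function(x) standardGeneric("exprState"))

#' Per-sample normalization factors
#' @param x an \linkS4class{ExpressionMatrix} at state \code{"normalized"}
#'   or later.
#' @return named numeric vector, one factor per sample.
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))

#' Gene lengths in base pairs
#' @param x a \linkS4class{CountMatrix}.
#' @return named numeric vector of gene lengths.
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' Planted ground-truth labels
#' @param x a \linkS4class{CountMatrix} produced by the synthetic-data
#'   generator.
#' @return list of truth labels (possibly empty).
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' Expression values
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return numeric matrix, genes x samples.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @describeIn CountMatrix raw count matrix.
#' @param object a \code{CountMatrix}.
#' @export
setMethod("counts", "CountMatrix", function(object) assay(object, "counts"))

#' @rdname geneLengths
#' @export
setMethod("geneLengths", "CountMatrix", function(x) {
  stats::setNames(rowData(x)$length_bp, rownames(x))
})

#' @rdname truthLabels
#' @export
setMethod("truthLabels", "CountMatrix", function(x) x@truth)

#' @rdname exprState
#' @export
setMethod("exprState", "ExpressionMatrix", function(x) x@state)

#' @rdname normFactors
#' @export
setMethod("normFactors", "ExpressionMatrix", function(x) {
  if (!x@state %in% c("normalized", "baselined"))
    stop("normalization factors are defined only from state 'normalized' on")
  stats::setNames(x@normFactors, colnames(x))
})

#' @rdname exprValues
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) assay(x, "exprs"))

#' Null-distribution accessors
#' @param x a \linkS4class{NullDistribution}.
#' @return \code{nullSamples}: integer vector of resampled overlap counts;
#'   \code{nullMean}/\code{nullSd}: numeric(1).
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))

#' @rdname nullSamples
#' @export
setGeneric("nullMean", function(x) standardGeneric("nullMean"))

#' @rdname nullSamples
#' @export
setGeneric("nullSd", function(x) standardGeneric("nullSd"))

#' @rdname nullSamples
#' @export
setMethod("nullSamples", "NullDistribution", function(x) x@samples)

#' @rdname nullSamples
#' @export
setMethod("nullMean", "NullDistribution", function(x) x@nullMean)

#' @rdname nullSamples
#' @export
setMethod("nullSd", "NullDistribution", function(x) x@nullSd)

setMethod("show", "CountMatrix", function(object) {
  cat("CountMatrix with", nrow(object), "genes and", ncol(object),
      "samples\n")
  cat("  cell types:",
      paste(unique(colData(object)$cell_type), collapse = ", "), "\n")
  cat("  treatments:",
      paste(unique(colData(object)$treatment), collapse = ", "), "\n")
  if (length(object@truth))
    cat("  planted truth:", paste(names(object@truth), collapse = ", "), "\n")
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix [", object@state, "] with ", nrow(object),
      " genes and ", ncol(object), " samples\n", sep = "")
  if (object@state %in% c("normalized", "baselined"))
    cat("  normalization factors: ",
        paste(sprintf("%.4g", object@normFactors), collapse = ", "), "\n",
        sep = "")
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution:", object@nIter, "iterations, mean",
      sprintf("%.4g", object@nullMean), ", sd",
      sprintf("%.4g", object@nullSd), "\n")
})
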