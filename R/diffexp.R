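#' @importFrom stats pf p.adjust model.matrix
NULL

.rss_under <- function(X, y) {
  # residual sum of squares of every column of y under design X
  Q <- qr.Q(qr(X))
  colSums(y^2) - colSums(crossprod(Q, y)^2)
}

#' Per-gene two-way ANOVA
#'
#' Fixed-effects two-way ANOVA (factors: cell type and treatment, with
#' their interaction when replication permits) fitted to every gene of a
#' baselined log2 expression matrix. Sums of squares are sequential in the
#' order cell type, treatment, interaction, computed for all genes at once
#' by projecting onto the QR bases of the nested design matrices; on
#' balanced designs this equals the classical orthogonal decomposition.
#' The interaction is retained only when the full model leaves at least 4
#' residual degrees of freedom; otherwise an additive model is fitted with
#' a warning. Genes with zero residual variance get p = 1 for every term.
#'
#' @param m an \linkS4class{ExpressionMatrix} at state \code{"baselined"}
#'   (restricted to filtered genes by the caller), or a plain genes x
#'   samples numeric matrix of log2 values.
#' @param design data.frame/DataFrame with \code{cell_type} and
#'   \code{treatment} per sample; defaults to \code{colData(m)}.
#' @return \code{DataFrame} with per-gene F statistics and p-values for the
#'   cell-type, treatment and (if fitted) interaction terms, plus the
#'   full-model omnibus test; metadata records whether the interaction was
#'   fitted and the residual degrees of freedom.
#' @export
twoWayAnova <- function(m, design = NULL) {
  if (is(m, "ExpressionMatrix")) {
    if (exprState(m) != "baselined")
      stop("two-way ANOVA expects baselined (log2) values")
    if (is.null(design)) design <- colData(m)
    vals <- exprValues(m)
  } else {
    vals <- as.matrix(m)
    if (is.null(design)) stop("a design is required for a plain matrix")
  }
  f_ct <- factor(design$cell_type)
  f_tr <- factor(design$treatment)
  if (nlevels(f_ct) < 2 || nlevels(f_tr) < 2)
    stop("both factors need at least two levels")
  y <- t(vals)
  n <- nrow(y)
  d <- data.frame(ct = f_ct, tr = f_tr)
  X1 <- model.matrix(~ct, d)
  X2 <- model.matrix(~ct + tr, d)
  X3 <- model.matrix(~ct * tr, d)
  df_res_full <- n - qr(X3)$rank
  with_int <- df_res_full >= 4
  if (!with_int)
    warning("interaction term dropped (", df_res_full,
            " residual df with interaction); fitting additive model")
  Xfull <- if (with_int) X3 else X2
  df_res <- n - qr(Xfull)$rank
  if (df_res < 1)
    stop("no residual degrees of freedom: drop the interaction term or ",
         "add replicates")
  ybar2 <- n * colMeans(y)^2
  rss0 <- colSums(y^2) - ybar2
  rss1 <- .rss_under(X1, y)
  rss2 <- .rss_under(X2, y)
  rss_full <- if (with_int) .rss_under(X3, y) else rss2
  df_ct <- qr(X1)$rank - 1L
  df_tr <- qr(X2)$rank - qr(X1)$rank
  df_int <- if (with_int) qr(X3)$rank - qr(X2)$rank else NA_integer_
  mse <- rss_full / df_res
  degenerate <- mse <= 1e-12 * (rss0 / max(1, n - 1) + 1e-12)
  f_of <- function(delta, df) {
    f <- (delta / df) / mse
    f[degenerate] <- NA_real_
    f
  }
  p_of <- function(f, df) {
    p <- pf(f, df, df_res, lower.tail = FALSE)
    p[degenerate] <- 1
    p
  }
  F_ct <- f_of(rss0 - rss1, df_ct)
  F_tr <- f_of(rss1 - rss2, df_tr)
  F_md <- f_of(rss0 - rss_full, ncol(Xfull) - 1L)
  out <- DataFrame(
    F_cell_type = F_ct, p_cell_type = p_of(F_ct, df_ct),
    F_treatment = F_tr, p_treatment = p_of(F_tr, df_tr),
    row.names = rownames(vals)
  )
  if (with_int) {
    F_int <- f_of(rss2 - rss_full, df_int)
    out$F_interaction <- F_int
    out$p_interaction <- p_of(F_int, df_int)
  } else {
    out$F_interaction <- NA_real_
    out$p_interaction <- NA_real_
  }
  out$F_model <- F_md
  out$p_model <- p_of(F_md, ncol(Xfull) - 1L)
  metadata(out) <- list(interaction = with_int, df_residual = df_res)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment \code{q_(i) = min_{j >= i} p_(j) * n / j}, capped at
#' 1 and mapped back to the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of BH-adjusted q-values.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-condition fold changes versus the untreated baseline
#'
#' For every (cell type, treatment) group, the ratio of that group's mean
#' normalized RPKM to the same cell type's baseline mean, per gene.
#' Reported as a linear fold change \code{max(r, 1/r) >= 1} with a
#' direction sign (+1 up, -1 down, 0 unchanged). Means are taken on the
#' linear scale.
#'
#' @param m an \linkS4class{ExpressionMatrix} at state \code{"normalized"}.
#' @param baseline baseline treatment label (default \code{"NS"}).
#' @return \code{DataFrame} with columns \code{fc_<ct>_<trt>} and
#'   \code{dir_<ct>_<trt>} for every non-baseline group.
#' @export
foldChanges <- function(m, baseline = "NS") {
  if (exprState(m) != "normalized")
    stop("fold changes are linear-scale ratios of normalized values")
  cd <- colData(m)
  v <- exprValues(m)
  out <- DataFrame(row.names = rownames(v))
  groups <- list()
  for (ct in unique(cd$cell_type)) {
    base_j <- which(cd$cell_type == ct & cd$treatment == baseline)
    if (!length(base_j))
      stop("no '", baseline, "' samples for cell type '", ct, "'")
    base_mean <- rowMeans(v[, base_j, drop = FALSE])
    for (trt in setdiff(unique(cd$treatment[cd$cell_type == ct]),
                        baseline)) {
      j <- which(cd$cell_type == ct & cd$treatment == trt)
      r <- rowMeans(v[, j, drop = FALSE]) / base_mean
      out[[paste("fc", ct, trt, sep = "_")]] <- pmax(r, 1 / r)
      out[[paste("dir", ct, trt, sep = "_")]] <- sign(r - 1)
      groups[[length(groups) + 1L]] <-
        data.frame(cell_type = ct, treatment = trt,
                   fc_col = paste("fc", ct, trt, sep = "_"))
    }
  }
  metadata(out)$groups <- do.call(rbind, groups)
  out
}

#' Differential-call gate
#'
#' A gene is called differential when \code{q < qCut} and
#' \code{fc > fcCut}, both strict, so a fold change of exactly 1.5 is not
#' called. Tightening either threshold can only shrink the called set.
#'
#' @param q BH-adjusted p-values.
#' @param fc linear fold changes (>= 1).
#' @param qCut,fcCut thresholds (defaults 0.05 and 1.5).
#' @return logical vector of calls.
#' @export
callDifferential <- function(q, fc, qCut = 0.05, fcCut = 1.5) {
  q < qCut & fc > fcCut
}

#' Differential-expression analysis
#'
#' Runs the per-gene two-way ANOVA on the baselined values, adjusts the
#' chosen omnibus p-value (treatment term by default, or the full-model
#' test) across genes by Benjamini-Hochberg, computes linear fold changes
#' versus the baseline treatment on the normalized values, and calls a
#' gene differential in a (cell type, treatment) group when
#' \code{q < qCut} and \code{fold change > fcCut} (both strict).
#'
#' @param baselined \linkS4class{ExpressionMatrix} at state
#'   \code{"baselined"}, restricted to the gene universe under test.
#' @param normalized \linkS4class{ExpressionMatrix} at state
#'   \code{"normalized"} on the same genes and samples.
#' @param omnibus which ANOVA p-value feeds the FDR adjustment:
#'   \code{"treatment"} (treatment term) or \code{"full"} (full model).
#' @param qCut,fcCut differential-call thresholds (defaults 0.05 and 1.5).
#' @param baseline baseline treatment label.
#' @return A \linkS4class{DEResult} with ANOVA statistics, \code{q}, fold
#'   changes and \code{de_<ct>_<trt>} call flags; thresholds and the
#'   omnibus convention are stored in its \code{metadata()}.
#' @export
differentialExpression <- function(baselined, normalized,
                                   omnibus = c("treatment", "full"),
                                   qCut = 0.05, fcCut = 1.5,
                                   baseline = "NS") {
  omnibus <- match.arg(omnibus)
  genes <- rownames(baselined)
  if (!all(genes %in% rownames(normalized)))
    stop("baselined and normalized matrices must share their gene universe")
  an <- twoWayAnova(baselined)
  fc <- foldChanges(normalized[genes, ], baseline = baseline)
  p_omni <- if (omnibus == "treatment") an$p_treatment else an$p_model
  q <- bhAdjust(p_omni)
  out <- an
  out$p_omnibus <- p_omni
  out$q <- q
  for (col in colnames(fc)) out[[col]] <- fc[[col]]
  groups <- metadata(fc)$groups
  groups$de_col <- sub("^fc", "de", groups$fc_col)
  for (i in seq_len(nrow(groups)))
    out[[groups$de_col[i]]] <- callDifferential(q, fc[[groups$fc_col[i]]],
                                                qCut, fcCut)
  metadata(out) <- c(metadata(an),
                     list(omnibus = omnibus, qCut = qCut, fcCut = fcCut,
                          baseline = baseline, groups = groups))
  new("DEResult", out)
}

#' Differential gene sets from a DEResult
#'
#' @param de a \linkS4class{DEResult}.
#' @return named list of gene-id vectors; names are
#'   \code{<cell type>.<treatment>} and each element also carries
#'   \code{cell_type}/\code{treatment} attributes.
#' @export
deSets <- function(de) {
  groups <- metadata(de)$groups
  sets <- lapply(seq_len(nrow(groups)), function(i) {
    s <- rownames(de)[de[[groups$de_col[i]]]]
    attr(s, "cell_type") <- groups$cell_type[i]
    attr(s, "treatment") <- groups$treatment[i]
    s
  })
  names(sets) <- paste(groups$cell_type, groups$treatment, sep = ".")
  sets
}
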