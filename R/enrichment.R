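#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges overlapsAny
#' @importFrom stats pnorm sd
NULL

#' Promoter window definition
#'
#' A window relative to the TSS: \code{upstream} bases before and
#' \code{downstream} bases after the first transcribed base, strand-aware.
#' The conventional definitions are (-1000, +500), (-1000, +1000) and
#' (-2000, +1).
#'
#' @param upstream,downstream window extent in bases
#'   (\code{upstream + downstream >= 1}).
#' @param label window label; defaults to \code{m<upstream>_p<downstream>}.
#' @return list with class \code{"PromoterWindowDef"}.
#' @export
promoterWindowDef <- function(upstream, downstream,
                              label = sprintf("m%d_p%d", upstream,
                                              downstream)) {
  if (upstream + downstream < 1)
    stop("window must span at least one base")
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream), label = label),
            class = "PromoterWindowDef")
}

#' @describeIn promoterWindowDef the three conventional promoter windows.
#' @export
standardWindowDefs <- function() {
  list(promoterWindowDef(1000L, 500L),
       promoterWindowDef(1000L, 1000L),
       promoterWindowDef(2000L, 1L))
}

#' Strand-aware promoter windows
#'
#' In 0-based half-open coordinates, a plus-strand TSS \code{t} yields
#' \code{[t - upstream, t + downstream)}; a minus-strand TSS yields the
#' mirror image \code{[t - downstream + 1, t + upstream + 1)}, the same
#' length. Windows are clamped to the chromosome bounds.
#'
#' @param genes character vector of gene ids (all must be annotated).
#' @param annotation annotation \code{GRanges} (see
#'   \code{\link{readAnnotation}}).
#' @param w a \code{\link{promoterWindowDef}}.
#' @return \code{GRanges} of promoter windows, named by gene.
#' @export
promoterWindows <- function(genes, annotation, w) {
  miss <- setdiff(genes, names(annotation))
  if (length(miss))
    stop("gene(s) absent from annotation: ",
         paste(utils::head(miss, 5), collapse = ", "))
  a <- annotation[genes]
  t0 <- start(a) - 1L
  plus <- as.character(strand(a)) == "+"
  s0 <- ifelse(plus, t0 - w$upstream, t0 - w$downstream + 1L)
  e0 <- ifelse(plus, t0 + w$downstream, t0 + w$upstream + 1L)
  s0 <- pmax(0L, s0)
  lens <- seqlengths(a)[as.character(seqnames(a))]
  e0 <- as.integer(e0)
  known <- !is.na(lens)
  e0[known] <- pmin(as.integer(lens[known]), e0[known])
  gr <- .bed_to_granges(as.character(seqnames(a)), as.integer(s0), e0,
                        seqlen = seqlengths(a))
  names(gr) <- genes
  gr
}

#' Observed overlap of input regions with a peak dataset
#'
#' The number of input regions sharing at least one base with at least one
#' peak; a region overlapping several peaks counts once. Strand is
#' ignored.
#'
#' @param regions input \code{GRanges} (e.g. promoter windows).
#' @param peaks peak \code{GRanges}.
#' @return non-negative integer count.
#' @export
observedOverlap <- function(regions, peaks) {
  sum(overlapsAny(regions, peaks, ignore.strand = TRUE))
}

#' Resampled empirical null of overlap counts
#'
#' Each iteration draws \code{inputSize} promoter windows uniformly
#' without replacement from the universe of all annotated promoters (same
#' window definition, hence the same region count and per-region length as
#' the input set) and records the observed overlap of the drawn set with
#' the peaks. Since regions are counted independently, the per-promoter
#' overlap indicator is precomputed once and each iteration sums it over
#' the drawn indices, which is exactly the overlap of the drawn set.
#'
#' @param inputSize number of regions in the input set.
#' @param universe \code{GRanges} of all promoter windows under the same
#'   window definition.
#' @param peaks peak \code{GRanges}.
#' @param nIter number of resampling iterations (default 2000).
#' @param seed RNG seed.
#' @return A \linkS4class{NullDistribution}.
#' @export
sampleNull <- function(inputSize, universe, peaks, nIter = 2000L,
                       seed = 1L) {
  n_univ <- length(universe)
  if (inputSize > n_univ)
    stop("input size (", inputSize, ") exceeds the promoter universe (",
         n_univ, ")")
  hits <- overlapsAny(universe, peaks, ignore.strand = TRUE)
  .withSeed(seed, {
    draws <- vapply(seq_len(nIter), function(i)
      sum(hits[sample.int(n_univ, inputSize)]), integer(1))
  })
  new("NullDistribution", samples = draws, nIter = as.integer(nIter),
      nullMean = mean(draws), nullSd = sd(draws), seed = as.integer(seed))
}

#' Z-score and p-value from an empirical null
#'
#' \code{z = (observed - mean) / sd} (sd with the n-1 denominator) and the
#' standard-normal tail probability: one-sided upper tail for enrichment
#' by default, or two-sided. A degenerate null (sd = 0) yields z = 0 and
#' p = 0.5 when the observation equals the null mean, and otherwise an
#' infinite z sentinel with p floored at 1e-300 (enrichment) or set to 1
#' (depletion), with the \code{degenerate} flag raised.
#'
#' @param observed observed overlap count.
#' @param null a \linkS4class{NullDistribution}.
#' @param tail \code{"one"} (upper-tail enrichment) or \code{"two"}.
#' @return list with \code{z}, \code{p}, \code{degenerate}.
#' @export
zPFromNull <- function(observed, null, tail = c("one", "two")) {
  tail <- match.arg(tail)
  mu <- nullMean(null)
  s <- nullSd(null)
  if (s > 0) {
    z <- (observed - mu) / s
    p <- if (tail == "one") pnorm(z, lower.tail = FALSE)
         else 2 * pnorm(abs(z), lower.tail = FALSE)
    return(list(z = z, p = max(p, 1e-300), degenerate = FALSE))
  }
  if (observed == mu)
    return(list(z = 0, p = 0.5, degenerate = TRUE))
  z <- if (observed > mu) Inf else -Inf
  p <- if (observed > mu || tail == "two") 1e-300 else 1
  list(z = z, p = p, degenerate = TRUE)
}

#' Enrichment of a gene set's promoters across a peak-dataset library
#'
#' For every (peak dataset, promoter window) pair: the observed overlap of
#' the gene set's promoter windows, a 2000-iteration resampled null from
#' size-matched random promoter draws, the resulting Z-score and p-value,
#' and a BH-adjusted q across the dataset library within each window.
#' Results are sorted by Z descending within each window. Per-dataset RNG
#' streams are derived deterministically from the master seed and the
#' dataset and window labels.
#'
#' @param genes character vector of input gene ids.
#' @param annotation annotation \code{GRanges} covering all genes.
#' @param peakLibrary named list of peak \code{GRanges}.
#' @param windows list of \code{\link{promoterWindowDef}}s (default: the
#'   three conventional definitions).
#' @param nIter resampling iterations per null (default 2000).
#' @param seed master RNG seed.
#' @param tail p-value tail convention (see \code{\link{zPFromNull}}).
#' @return An \linkS4class{EnrichmentResult} with columns
#'   \code{dataset_id}, \code{window}, \code{input_size}, \code{observed},
#'   \code{null_mean}, \code{null_sd}, \code{z}, \code{p}, \code{q},
#'   \code{degenerate}.
#' @export
enrichLibrary <- function(genes, annotation, peakLibrary,
                          windows = standardWindowDefs(), nIter = 2000L,
                          seed = 1L, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (!length(genes)) stop("the input gene set is empty")
  if (!length(peakLibrary)) stop("the peak library is empty")
  if (is.null(names(peakLibrary)))
    names(peakLibrary) <- vapply(peakLibrary, function(g) {
      id <- metadata(g)$dataset_id
      if (is.null(id)) stop("unnamed peak dataset") else id
    }, character(1))
  blocks <- list()
  for (w in windows) {
    universe <- promoterWindows(names(annotation), annotation, w)
    input <- universe[genes]
    obs <- vapply(peakLibrary, function(pk) observedOverlap(input, pk),
                  integer(1))
    rows <- lapply(names(peakLibrary), function(d) {
      nd <- sampleNull(length(input), universe, peakLibrary[[d]],
                       nIter = nIter,
                       seed = deriveSeed(seed, paste(d, w$label)))
      zp <- zPFromNull(obs[[d]], nd, tail = tail)
      DataFrame(dataset_id = d, window = w$label,
                input_size = length(input), observed = obs[[d]],
                null_mean = nullMean(nd), null_sd = nullSd(nd),
                z = zp$z, p = zp$p, degenerate = zp$degenerate)
    })
    blk <- do.call(rbind, rows)
    blk$q <- bhAdjust(blk$p)
    blocks[[w$label]] <- blk[order(-blk$z), ]
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  metadata(out) <- list(nIter = nIter, seed = seed, tail = tail)
  new("EnrichmentResult", out)
}
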