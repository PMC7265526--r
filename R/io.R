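#' @importFrom utils read.delim write.table
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

# All on-disk genomic coordinates are 0-based half-open (BED convention);
# in-memory GRanges follow the Bioconductor 1-based closed convention, and
# the converters below are the only places the +-1 shift happens.

.bed_to_granges <- function(chrom, start0, end0, seqlen = NULL) {
  gr <- GRanges(chrom, IRanges(start = start0 + 1L, end = end0))
  if (!is.null(seqlen))
    seqlengths(gr) <- seqlen[seqlevels(gr)]
  gr
}

.granges_to_bed <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr))
}

#' Read a gene-level counts table with its sample metadata
#'
#' The counts table is tab-separated with header columns \code{gene_id},
#' \code{length_bp}, then one column per sample. The metadata table maps
#' \code{sample_id} to \code{cell_type}, \code{treatment} and
#' \code{replicate}.
#'
#' @param path path to the counts table.
#' @param metadataPath path to the sample metadata table.
#' @return A \linkS4class{CountMatrix}.
#' @export
readCountsTable <- function(path, metadataPath) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% colnames(tab)))
    stop("counts table must have 'gene_id' and 'length_bp' columns")
  meta <- read.delim(metadataPath, stringsAsFactors = FALSE)
  sample_cols <- setdiff(colnames(tab), c("gene_id", "length_bp"))
  cts <- as.matrix(tab[, sample_cols, drop = FALSE])
  rownames(cts) <- tab$gene_id
  bad <- which(is.na(cts) | cts < 0 | cts != round(cts), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at gene '%s', sample '%s'",
                 rownames(cts)[bad[1, 1]], colnames(cts)[bad[1, 2]]))
  if (any(tab$length_bp <= 0))
    stop("gene lengths must be positive (gene '",
         tab$gene_id[which(tab$length_bp <= 0)[1]], "')")
  storage.mode(cts) <- "integer"
  CountMatrix(cts, tab$length_bp, meta)
}

#' @describeIn readCountsTable write a \code{CountMatrix} back to a counts
#'   table and a metadata table.
#' @param x a \linkS4class{CountMatrix}.
#' @export
writeCountsTable <- function(x, path, metadataPath) {
  tab <- data.frame(gene_id = rownames(x),
                    length_bp = rowData(x)$length_bp,
                    counts(x), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(x),
                     cell_type = colData(x)$cell_type,
                     treatment = colData(x)$treatment,
                     replicate = colData(x)$replicate)
  write.table(meta, metadataPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a promoter annotation
#'
#' The annotation is tab-separated with columns \code{gene_id},
#' \code{chrom}, \code{tss}, \code{strand}; \code{tss} is the 0-based
#' position of the first transcribed base. A companion chromosome-sizes
#' table (\code{chrom}, \code{length}) defines the coordinate bounds.
#'
#' @param path path to the annotation table.
#' @param chromSizesPath path to the chromosome-sizes table.
#' @return A width-1 \link[GenomicRanges]{GRanges} at each TSS, named by
#'   gene, with strand and seqlengths set. The stored (1-based) position is
#'   \code{tss + 1}.
#' @export
readAnnotation <- function(path, chromSizesPath) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer",
                                   "character"))
  sizes <- read.delim(chromSizesPath, stringsAsFactors = FALSE)
  .makeAnnotation(tab$gene_id, tab$chrom, tab$tss, tab$strand,
                  stats::setNames(sizes$length, sizes$chrom))
}

.makeAnnotation <- function(gene_id, chrom, tss, strand, chrom_sizes) {
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in annotation: ",
         gene_id[anyDuplicated(gene_id)])
  bad_strand <- !strand %in% c("+", "-")
  if (any(bad_strand))
    stop("invalid strand '", strand[which(bad_strand)[1]], "' for gene '",
         gene_id[which(bad_strand)[1]], "' (must be + or -)")
  if (any(is.na(tss)) || any(tss < 0))
    stop("tss must be a non-negative integer")
  missing_chrom <- setdiff(unique(chrom), names(chrom_sizes))
  if (length(missing_chrom))
    stop("chromosome(s) absent from sizes table: ",
         paste(missing_chrom, collapse = ", "))
  over <- tss >= chrom_sizes[chrom]
  if (any(over))
    stop("tss beyond chromosome end for gene '", gene_id[which(over)[1]], "'")
  gr <- GRanges(chrom, IRanges(tss + 1L, width = 1L), strand = strand)
  names(gr) <- gene_id
  seqlengths(gr) <- chrom_sizes[seqlevels(gr)]
  gr
}

#' @describeIn readAnnotation write an annotation and its chromosome sizes.
#' @param anno annotation \code{GRanges} as returned by
#'   \code{readAnnotation}.
#' @export
writeAnnotation <- function(anno, path, chromSizesPath) {
  tab <- data.frame(gene_id = names(anno),
                    chrom = as.character(seqnames(anno)),
                    tss = start(anno) - 1L,
                    strand = as.character(strand(anno)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sl <- seqlengths(anno)
  write.table(data.frame(chrom = names(sl), length = unname(sl)),
              chromSizesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3+ peak file
#'
#' Coordinates are 0-based half-open. Malformed lines are hard errors,
#' never skipped: non-numeric coordinates and empty intervals
#' (\code{start >= end}) abort with the offending line number.
#'
#' @param path path to a tab-separated BED file.
#' @param name dataset identifier; defaults to the file stem.
#' @return A \link[GenomicRanges]{GRanges} of peaks; the dataset identifier
#'   is stored in \code{metadata(x)$dataset_id}.
#' @export
readBed <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.bed$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    gr <- GRanges()
    metadata(gr)$dataset_id <- name
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L)))
  bad_num <- is.na(start0) | is.na(end0)
  if (any(bad_num))
    stop("BED line ", which(bad_num)[1], ": non-numeric coordinate")
  bad_iv <- start0 >= end0 | start0 < 0
  if (any(bad_iv))
    stop("BED line ", which(bad_iv)[1],
         ": invalid interval (requires 0 <= start < end)")
  gr <- .bed_to_granges(chrom, start0, end0)
  metadata(gr)$dataset_id <- name
  gr
}

#' @describeIn readBed write peaks as BED3, sorted by (chrom, start).
#' @param peaks a peak \code{GRanges}.
#' @export
writeBed <- function(peaks, path) {
  bed <- .granges_to_bed(peaks)
  bed <- bed[order(bed$chrom, bed$start, bed$end), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(bed))
    writeLines(paste(bed$chrom, bed$start, bed$end, sep = "\t"), con)
  invisible(path)
}

#' Write a results table
#'
#' Writes a \linkS4class{DEResult} or \linkS4class{EnrichmentResult} (or any
#' DataFrame) as a tab-separated table with a fixed column order (the order
#' of the object's columns) and full floating-point precision (well beyond
#' 6 significant digits).
#'
#' @param x the result object.
#' @param path output path.
#' @export
writeResultsTable <- function(x, path) {
  df <- as.data.frame(x)
  if (!is.null(rownames(df)) && !identical(rownames(df),
                                           as.character(seq_len(nrow(df)))))
    df <- cbind(gene_id = rownames(df), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain gene list (one identifier per line)
#' @param path file with one gene id per line.
#' @return character vector of gene ids.
#' @export
readGeneList <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}
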