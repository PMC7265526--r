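#' @importFrom stats rnbinom rpois rbinom runif setNames
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic study generator. The defaults emulate a
#' two-cell-type (adipocyte, macrophage) by four-treatment (NS, IFNB, LPS,
#' IFNB_LPS) stimulation experiment: negative-binomial gene-level counts
#' whose means carry cell-type identity programs, single-treatment response
#' programs (each induced by one stimulus, alone or in combination, either
#' in both cell types or in one), and a dormant convergence program induced
#' in \emph{both} cell types only under the combined treatment. Under the
#' combined treatment the identity programs are partially attenuated
#' (\code{identityAttenuation}), so the two transcriptomes converge.
#'
#' @slot nGenes integer(1); total genes (default 2000).
#' @slot cellTypes character(2); cell-type labels.
#' @slot treatments character; treatment labels, the first being the
#'   untreated baseline ("NS").
#' @slot nReplicates integer(1); replicates per (cell type, treatment);
#'   default 3 for stable ANOVA, the study-like preset uses 2.
#' @slot nbDispersion numeric(1); negative-binomial dispersion
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @slot baseMeanLog2,baseSdLog2 numeric(1); per-gene baseline log2
#'   expression is drawn N(baseMeanLog2, baseSdLog2).
#' @slot libraryScaleFactors numeric; per-sample depth multipliers (empty =
#'   all 1); recycled checkably to the sample count.
#' @slot nIdentityGenes integer(1); identity-program size per cell type.
#' @slot identityEffectLog2 numeric(1); log2 effect of identity programs.
#' @slot nSharedResponseGenes named integer; per single treatment, genes
#'   induced in both cell types by that treatment (alone or combined).
#' @slot nPrivateResponseGenes named integer; per single treatment, genes
#'   induced in one cell type only (the first cell type for the first
#'   single treatment, the second for the second).
#' @slot responseEffectLog2 numeric(1); log2 effect of response programs.
#' @slot nDormantGenes integer(1); dormant-convergence program size.
#' @slot dormantEffectLog2 numeric(1); log2 effect of the dormant program
#'   under combined treatment (both cell types).
#' @slot identityAttenuation numeric(1) in [0,1]; fraction of the identity
#'   effect removed under combined treatment.
#' @slot chromLengths named numeric; chromosome lengths for the synthetic
#'   annotation.
#' @slot rngSeed integer(1); default RNG seed.
#' @export
setClass("SimulationConfig", slots = c(
  nGenes = "integer", cellTypes = "character", treatments = "character",
  nReplicates = "integer", nbDispersion = "numeric",
  baseMeanLog2 = "numeric", baseSdLog2 = "numeric",
  libraryScaleFactors = "numeric",
  nIdentityGenes = "integer", identityEffectLog2 = "numeric",
  nSharedResponseGenes = "integer", nPrivateResponseGenes = "integer",
  responseEffectLog2 = "numeric",
  nDormantGenes = "integer", dormantEffectLog2 = "numeric",
  identityAttenuation = "numeric",
  chromLengths = "numeric", rngSeed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(object@cellTypes) != 2L)
    msg <- c(msg, "exactly two cell types are supported")
  if (length(object@treatments) < 2L)
    msg <- c(msg, "need a baseline plus at least one treatment")
  if (anyDuplicated(c(object@cellTypes)) || anyDuplicated(object@treatments))
    msg <- c(msg, "cell-type and treatment labels must be unique")
  if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
  n_prog <- 2L * object@nIdentityGenes + sum(object@nSharedResponseGenes) +
    sum(object@nPrivateResponseGenes) + object@nDormantGenes
  if (n_prog > object@nGenes)
    msg <- c(msg, "program sizes exceed nGenes (programs must be disjoint)")
  if (length(object@libraryScaleFactors) &&
      any(object@libraryScaleFactors <= 0))
    msg <- c(msg, "library scale factors must be positive")
  eff <- c(object@identityEffectLog2, object@responseEffectLog2,
           object@dormantEffectLog2)
  if (any(!is.finite(eff))) msg <- c(msg, "effect sizes must be finite")
  if (object@identityAttenuation < 0 || object@identityAttenuation > 1)
    msg <- c(msg, "identityAttenuation must lie in [0, 1]")
  if (any(object@chromLengths <= 0) || is.null(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must be a named vector of positive lengths")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig constructor with study-emulating defaults.
#' @param studyLike logical; if TRUE use n = 2 replicates per condition as
#'   in the emulated study design (default FALSE: n = 3).
#' @param ... slot overrides, e.g. \code{nGenes = 6000}.
#' @return A validated \code{SimulationConfig}.
#' @export
simulationConfig <- function(..., studyLike = FALSE) {
  args <- list(...)
  defaults <- list(
    nGenes = 2000L,
    cellTypes = c("adipocyte", "macrophage"),
    treatments = c("NS", "IFNB", "LPS", "IFNB_LPS"),
    nReplicates = if (studyLike) 2L else 3L,
    nbDispersion = 0.05,
    baseMeanLog2 = 5, baseSdLog2 = 1.5,
    libraryScaleFactors = numeric(0),
    nIdentityGenes = 100L, identityEffectLog2 = 4,
    nSharedResponseGenes = c(IFNB = 60L, LPS = 40L),
    nPrivateResponseGenes = c(IFNB = 60L, LPS = 80L),
    responseEffectLog2 = 2,
    nDormantGenes = 500L, dormantEffectLog2 = 2.5,
    identityAttenuation = 0.5,
    chromLengths = c(chr1 = 60e6, chr2 = 45e6, chr3 = 30e6),
    rngSeed = 1L
  )
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  int_slots <- c("nGenes", "nReplicates", "nIdentityGenes",
                 "nSharedResponseGenes", "nPrivateResponseGenes",
                 "nDormantGenes", "rngSeed")
  for (s in int_slots) {
    nm <- names(defaults[[s]])
    defaults[[s]] <- as.integer(defaults[[s]])
    names(defaults[[s]]) <- nm
  }
  do.call(new, c(list("SimulationConfig"), defaults))
}

#' @describeIn SimulationConfig read a configuration from a YAML file.
#' @param path YAML file whose top-level keys are constructor arguments.
#' @export
readSimulationConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in c("nSharedResponseGenes", "nPrivateResponseGenes",
               "chromLengths"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  do.call(simulationConfig, vals)
}

.geneIds <- function(n) sprintf("g%05d", seq_len(n))

# Disjoint program membership, assigned to the leading gene indices in a
# fixed order so membership is reproducible from the config alone.
.assignPrograms <- function(config) {
  ids <- .geneIds(config@nGenes)
  cursor <- 0L
  take <- function(n) {
    out <- ids[seq_len(n) + cursor]
    cursor <<- cursor + n
    out
  }
  ct <- config@cellTypes
  single <- setdiff(config@treatments, config@treatments[1])
  combined <- single[length(single)]
  single <- setdiff(single, combined)
  programs <- list()
  for (k in ct)
    programs[[paste0("identity_", k)]] <- take(config@nIdentityGenes)
  for (tr in names(config@nSharedResponseGenes))
    programs[[paste0("shared_", tr)]] <-
      take(config@nSharedResponseGenes[[tr]])
  private_ct <- setNames(ct[seq_along(config@nPrivateResponseGenes)],
                         names(config@nPrivateResponseGenes))
  for (tr in names(config@nPrivateResponseGenes))
    programs[[paste0("private_", tr)]] <-
      take(config@nPrivateResponseGenes[[tr]])
  programs$dormant <- take(config@nDormantGenes)
  list(programs = programs, private_ct = private_ct,
       single = single, combined = combined)
}

# log2 expression offset of each gene in one (cell type, treatment) group
.groupEffects <- function(config, assign, ct, trt) {
  eff <- setNames(numeric(config@nGenes), .geneIds(config@nGenes))
  id_scale <- if (trt == assign$combined) 1 - config@identityAttenuation
              else 1
  eff[assign$programs[[paste0("identity_", ct)]]] <-
    config@identityEffectLog2 * id_scale
  for (tr in names(config@nSharedResponseGenes))
    if (trt %in% c(tr, assign$combined))
      eff[assign$programs[[paste0("shared_", tr)]]] <-
        eff[assign$programs[[paste0("shared_", tr)]]] +
        config@responseEffectLog2
  for (tr in names(config@nPrivateResponseGenes))
    if (trt %in% c(tr, assign$combined) && ct == assign$private_ct[[tr]])
      eff[assign$programs[[paste0("private_", tr)]]] <-
        eff[assign$programs[[paste0("private_", tr)]]] +
        config@responseEffectLog2
  if (trt == assign$combined)
    eff[assign$programs$dormant] <- eff[assign$programs$dormant] +
      config@dormantEffectLog2
  eff
}

.rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu,
                                                 size = 1 / dispersion)
}

#' Simulate a gene-level count matrix with planted structure
#'
#' Counts are negative-binomial with mean
#' \code{2^(base + effects) * length/1000 * scale} per gene and sample,
#' where the effects encode the programs described in
#' \linkS4class{SimulationConfig}. Gene lengths are uniform on
#' [500, 10000] bp. Deterministic given the seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed RNG seed; defaults to the config's seed.
#' @return A \linkS4class{CountMatrix}; planted truth (program membership,
#'   per-sample true scale factors, per-group log2 means) is available via
#'   \code{\link{truthLabels}}.
#' @export
simulateExpression <- function(config, seed = config@rngSeed) {
  validObject(config)
  assign <- .assignPrograms(config)
  design <- expand.grid(replicate = seq_len(config@nReplicates),
                        treatment = config@treatments,
                        cell_type = config@cellTypes,
                        stringsAsFactors = FALSE)
  design <- design[, c("cell_type", "treatment", "replicate")]
  design$sample_id <- paste(design$cell_type, design$treatment,
                            design$replicate, sep = "_")
  n_samp <- nrow(design)
  scale <- config@libraryScaleFactors
  if (!length(scale)) scale <- rep(1, n_samp)
  if (length(scale) != n_samp)
    stop("libraryScaleFactors must have one entry per sample (", n_samp, ")")
  ids <- .geneIds(config@nGenes)
  .withSeed(seed, {
    lengths_bp <- round(runif(config@nGenes, 500, 10000))
    base <- stats::rnorm(config@nGenes, config@baseMeanLog2,
                         config@baseSdLog2)
    cts <- matrix(0L, config@nGenes, n_samp,
                  dimnames = list(ids, design$sample_id))
    for (j in seq_len(n_samp)) {
      eff <- .groupEffects(config, assign, design$cell_type[j],
                           design$treatment[j])
      mu <- 2^(base + eff) * (lengths_bp / 1000) * scale[j]
      cts[, j] <- .rcounts(config@nGenes, mu, config@nbDispersion)
    }
  })
  storage.mode(cts) <- "integer"
  truth <- list(programs = assign$programs,
                scaleFactors = setNames(scale, design$sample_id),
                baseLog2 = setNames(base, ids),
                combinedTreatment = assign$combined,
                config = config)
  CountMatrix(cts, lengths_bp, design, truth = truth)
}

#' Simulate an expression matrix with planted per-sample scale factors
#'
#' Generates a genes x samples expression matrix (negative-binomial values
#' around a per-gene baseline) in which column \code{s} is scaled by the
#' planted factor \code{scaleFactors[s]} and no gene carries any
#' differential effect. Used to validate that the median-of-ratios
#' normalization factors recover planted depth differences.
#'
#' @param nGenes number of genes.
#' @param scaleFactors named positive numeric vector, one per sample.
#' @param baseMeanLog2,baseSdLog2 baseline log2 expression distribution.
#' @param dispersion negative-binomial dispersion of the values.
#' @param seed RNG seed.
#' @return list with \code{expr} (an \linkS4class{ExpressionMatrix} at state
#'   \code{"raw"}) and \code{scaleFactors} (the planted truth).
#' @export
simulateScaledExpression <- function(nGenes, scaleFactors,
                                     baseMeanLog2 = 5, baseSdLog2 = 1.5,
                                     dispersion = 0.05, seed = 1L) {
  if (any(scaleFactors <= 0)) stop("scale factors must be positive")
  n_samp <- length(scaleFactors)
  if (is.null(names(scaleFactors)))
    names(scaleFactors) <- sprintf("s%02d", seq_len(n_samp))
  ids <- .geneIds(nGenes)
  .withSeed(seed, {
    base <- 2^stats::rnorm(nGenes, baseMeanLog2, baseSdLog2)
    vals <- vapply(seq_len(n_samp), function(j)
      .rcounts(nGenes, base * scaleFactors[j], dispersion),
      numeric(nGenes))
  })
  dimnames(vals) <- list(ids, names(scaleFactors))
  cd <- DataFrame(cell_type = rep("synthetic", n_samp),
                  treatment = rep("NS", n_samp),
                  replicate = seq_len(n_samp),
                  row.names = names(scaleFactors))
  se <- SummarizedExperiment(assays = list(exprs = vals), colData = cd)
  expr <- new("ExpressionMatrix", se, state = "raw",
              normFactors = numeric(0), floor = NA_real_)
  list(expr = expr, scaleFactors = scaleFactors)
}

#' Simulate a promoter annotation
#'
#' Places one TSS per gene uniformly on the configured chromosomes with at
#' least 5 kb clearance from either end; strands are Bernoulli(0.5).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed RNG seed; defaults to the config's seed.
#' @return annotation \code{GRanges} as from \code{\link{readAnnotation}}.
#' @export
simulateAnnotation <- function(config, seed = config@rngSeed) {
  validObject(config)
  clear <- 5000
  lens <- config@chromLengths
  if (any(lens <= 2 * clear))
    stop("every chromosome must exceed ", 2 * clear, " bp")
  ids <- .geneIds(config@nGenes)
  .withSeed(seed, {
    chrom <- sample(names(lens), config@nGenes, replace = TRUE,
                    prob = lens / sum(lens))
    tss <- floor(runif(config@nGenes, clear, lens[chrom] - clear))
    strand <- ifelse(runif(config@nGenes) < 0.5, "+", "-")
  })
  .makeAnnotation(ids, chrom, as.integer(tss), strand, lens)
}

#' Simulate a library of peak datasets with planted enrichment
#'
#' For each dataset, every gene's promoter receives a peak of width
#' \code{peakWidth} centered on its TSS with probability \code{pFg} if the
#' gene belongs to that dataset's target set and \code{pBg} otherwise;
#' \code{nDecoys} additional peaks are placed uniformly per dataset.
#'
#' @param annotation annotation \code{GRanges}.
#' @param nDatasets number of datasets in the library.
#' @param enriched named list mapping dataset id to a character vector of
#'   target genes; dataset ids default to \code{ds01, ds02, ...}.
#' @param pFg,pBg hit probabilities for target and background genes
#'   (\code{0 <= pBg <= pFg <= 1}).
#' @param peakWidth peak width in bp.
#' @param nDecoys intergenic decoy peaks per dataset.
#' @param seed RNG seed.
#' @return list with \code{datasets} (named list of peak \code{GRanges})
#'   and \code{truth} (enrichment flags and target sets).
#' @export
simulatePeakLibrary <- function(annotation, nDatasets, enriched = list(),
                                pFg = 0.8, pBg = 0.1, peakWidth = 200L,
                                nDecoys = 200L, seed = 1L) {
  if (pBg < 0 || pFg > 1 || pBg > pFg)
    stop("hit probabilities must satisfy 0 <= pBg <= pFg <= 1")
  ds_ids <- sprintf("ds%02d", seq_len(nDatasets))
  if (length(enriched)) {
    if (is.null(names(enriched)) ||
        !all(names(enriched) %in% ds_ids))
      stop("names of 'enriched' must be dataset ids among: ",
           paste(utils::head(ds_ids, 3), collapse = ", "), ", ...")
    bad <- setdiff(unique(unlist(enriched)), names(annotation))
    if (length(bad))
      stop("target gene(s) absent from annotation: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  lens <- seqlengths(annotation)
  tss0 <- start(annotation) - 1L
  chrom <- as.character(seqnames(annotation))
  half <- peakWidth %/% 2L
  datasets <- vector("list", nDatasets)
  names(datasets) <- ds_ids
  .withSeed(seed, {
    for (d in ds_ids) {
      p <- rep(pBg, length(annotation))
      if (d %in% names(enriched))
        p[names(annotation) %in% enriched[[d]]] <- pFg
      hit <- runif(length(annotation)) < p
      s0 <- pmax(0L, tss0[hit] - half)
      e0 <- pmin(as.integer(lens[chrom[hit]]), s0 + as.integer(peakWidth))
      dchrom <- sample(names(lens), nDecoys, replace = TRUE,
                       prob = lens / sum(lens))
      ds0 <- floor(runif(nDecoys, 0, lens[dchrom] - peakWidth))
      gr <- .bed_to_granges(c(chrom[hit], dchrom),
                            as.integer(c(s0, ds0)),
                            as.integer(c(e0, ds0 + peakWidth)),
                            seqlen = lens)
      metadata(gr)$dataset_id <- d
      datasets[[d]] <- gr
    }
  })
  truth <- list(enriched = enriched,
                isEnriched = setNames(ds_ids %in% names(enriched), ds_ids),
                pFg = pFg, pBg = pBg, peakWidth = peakWidth)
  list(datasets = datasets, truth = truth)
}
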