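#' Configuration for the synthetic expression generator
#'
#' Describes a planted-structure expression dataset: block-correlated gene
#' modules driven by shared latent factors, a subset of modules carrying a
#' class-dependent mean shift on a fraction of their genes, per-(batch, gene)
#' additive and multiplicative batch effects, and a planted annotation gene
#' set overlapping the first discriminative module. Values are written on a
#' microarray-like intensity scale (2^(x + 8)) so that the log2 step of the
#' preprocessing module is exercised.
#'
#' @param nGenes total number of genes; genes not claimed by a module are
#'   independent background genes.
#' @param nSamples,nCase total samples and number of cases (rest controls).
#' @param moduleSizes integer vector of module sizes (sum must be <= nGenes).
#' @param withinModuleCor target expected pairwise Pearson correlation within
#'   a module, in (0, 1). Gene g of module m is
#'   `sqrt(rho) * F_m + sqrt(1 - rho) * eps_g` with standard-normal factor and
#'   noise, so the expected correlation equals rho exactly.
#' @param discriminativeModules indices of modules carrying class signal.
#' @param effectSize class mean difference on informative genes, in units of
#'   the per-gene marginal SD (which is 1 by construction).
#' @param informativeFraction fraction of each discriminative module's genes
#'   that carry the shift, in (0, 1].
#' @param nBatches number of batches; samples are assigned round-robin within
#'   each class so every batch contains both classes.
#' @param batchShiftSd,batchScaleSd SDs of the per-(batch, gene) additive
#'   shift and log-scale factor (0 disables the effect).
#' @param annotationSize,annotationOverlap total size of the planted
#'   annotation set and how many of its genes sit inside the first
#'   discriminative module.
#' @param seed integer seed; the generator is byte-reproducible given the
#'   configuration and seed.
#' @return a validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nGenes = 300L, nSamples = 100L, nCase = 50L,
                            moduleSizes = rep(20L, 6L),
                            withinModuleCor = 0.8,
                            discriminativeModules = c(1L, 2L),
                            effectSize = 1.0, informativeFraction = 0.5,
                            nBatches = 1L, batchShiftSd = 0,
                            batchScaleSd = 0, annotationSize = 10L,
                            annotationOverlap = 6L, seed = 1L) {
  nGenes <- .assertScalarCount(nGenes, "nGenes")
  nSamples <- .assertScalarCount(nSamples, "nSamples")
  nCase <- .assertScalarCount(nCase, "nCase")
  if (nCase >= nSamples) stop("invalid 'nCase': must be < nSamples")
  if (length(moduleSizes) < 1 || any(moduleSizes < 1) ||
      any(moduleSizes != round(moduleSizes)))
    stop("invalid 'moduleSizes': positive counts required")
  moduleSizes <- as.integer(moduleSizes)
  if (sum(moduleSizes) > nGenes)
    stop("invalid 'moduleSizes': sum exceeds nGenes")
  .assertFraction(withinModuleCor, "withinModuleCor")
  if (length(discriminativeModules) > 0 &&
      !all(discriminativeModules %in% seq_along(moduleSizes)))
    stop("invalid 'discriminativeModules': unknown module index")
  if (!is.numeric(effectSize) || length(effectSize) != 1 || effectSize < 0)
    stop("invalid 'effectSize': nonnegative real required")
  .assertFraction(informativeFraction, "informativeFraction", hiOpen = FALSE)
  nBatches <- .assertScalarCount(nBatches, "nBatches")
  if (batchShiftSd < 0) stop("invalid 'batchShiftSd': must be >= 0")
  if (batchScaleSd < 0) stop("invalid 'batchScaleSd': must be >= 0")
  annotationSize <- .assertScalarCount(annotationSize, "annotationSize")
  if (length(discriminativeModules) > 0) {
    desig <- moduleSizes[discriminativeModules[1]]
    if (annotationOverlap > annotationSize || annotationOverlap > desig)
      stop("invalid 'annotationOverlap': must be <= annotationSize and <= designated module size")
  }
  structure(list(
    nGenes = nGenes, nSamples = nSamples, nCase = nCase,
    moduleSizes = moduleSizes, withinModuleCor = withinModuleCor,
    discriminativeModules = as.integer(discriminativeModules),
    effectSize = effectSize, informativeFraction = informativeFraction,
    nBatches = nBatches, batchShiftSd = batchShiftSd,
    batchScaleSd = batchScaleSd, annotationSize = annotationSize,
    annotationOverlap = as.integer(annotationOverlap),
    seed = as.integer(seed)), class = "SyntheticConfig")
}

#' Generate a synthetic expression dataset with known planted structure
#'
#' @param config a [syntheticConfig()] object.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"exprs"` (intensity scale), `colData` columns `class` and `batch`,
#'   `rowData` columns `module` (0 = background) and `informative`, and the
#'   full ground truth under `metadata(se)$groundTruth`.
#' @details All random draws happen in a fixed order regardless of parameter
#'   values (effect size, batch SDs), so datasets generated from configs that
#'   differ only in those parameters share the same noise realisation —
#'   convenient for matched-seed comparisons.
#' @export
simulateCoexpression <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    config <- do.call(syntheticConfig, config)
  set.seed(config$seed)
  nG <- config$nGenes; nS <- config$nSamples
  nMod <- length(config$moduleSizes)
  rho <- config$withinModuleCor

  geneIds <- sprintf("g%04d", seq_len(nG))
  sampleIds <- sprintf("s%03d", seq_len(nS))
  moduleOf <- integer(nG)
  pos <- 1L
  for (m in seq_len(nMod)) {
    moduleOf[pos:(pos + config$moduleSizes[m] - 1L)] <- m
    pos <- pos + config$moduleSizes[m]
  }

  classes <- rep("control", nS)
  classes[seq_len(config$nCase)] <- "case"
  batches <- character(nS)
  for (cl in c("case", "control")) {
    idx <- which(classes == cl)
    batches[idx] <- sprintf("b%d", rep_len(seq_len(config$nBatches), length(idx)))
  }

  # fixed draw order: factors, noise, batch effects
  Fm <- matrix(rnorm(nMod * nS), nMod, nS)
  eps <- matrix(rnorm(nG * nS), nG, nS)
  shift <- matrix(rnorm(config$nBatches * nG), config$nBatches, nG) *
    config$batchShiftSd
  logScale <- matrix(rnorm(config$nBatches * nG), config$nBatches, nG) *
    config$batchScaleSd

  x <- eps
  inMod <- moduleOf > 0L
  x[inMod, ] <- sqrt(rho) * Fm[moduleOf[inMod], , drop = FALSE] +
    sqrt(1 - rho) * eps[inMod, , drop = FALSE]

  informative <- logical(nG)
  for (m in config$discriminativeModules) {
    genes <- which(moduleOf == m)
    nInf <- max(1L, round(config$informativeFraction * length(genes)))
    informative[genes[seq_len(nInf)]] <- TRUE
  }
  if (any(informative))
    x[informative, classes == "case"] <-
      x[informative, classes == "case"] + config$effectSize

  batchIdx <- as.integer(sub("^b", "", batches))
  for (b in seq_len(config$nBatches)) {
    sel <- batchIdx == b
    if (!any(sel)) next
    x[, sel] <- x[, sel] * exp(logScale[b, ]) + shift[b, ]
  }

  annotation <- character(0)
  if (length(config$discriminativeModules) > 0 && config$annotationSize > 0) {
    desig <- which(moduleOf == config$discriminativeModules[1])
    annotation <- geneIds[desig[seq_len(config$annotationOverlap)]]
    nOut <- config$annotationSize - config$annotationOverlap
    if (nOut > 0) {
      background <- which(moduleOf == 0L)
      if (length(background) < nOut)
        stop("not enough background genes for the annotation set")
      annotation <- c(annotation, geneIds[background[seq_len(nOut)]])
    }
  }

  intensity <- 2^(x + 8)
  dimnames(intensity) <- list(geneIds, sampleIds)
  truth <- list(
    module_of_gene = setNames(moduleOf, geneIds),
    informative_genes = geneIds[informative],
    discriminative_modules = config$discriminativeModules,
    batch_of_sample = setNames(batches, sampleIds),
    class_of_sample = setNames(classes, sampleIds),
    annotation_set = annotation)

  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = intensity),
    rowData = S4Vectors::DataFrame(module = moduleOf,
                                   informative = informative,
                                   row.names = geneIds),
    colData = S4Vectors::DataFrame(class = classes, batch = batches,
                                   row.names = sampleIds),
    metadata = list(groundTruth = truth, config = config))
}

#' Generate a two-level nested module structure
#'
#' Genes in the same sub-block correlate at `rhoSub`; genes in the same
#' super-block but different sub-blocks correlate at `rhoSuper`; genes in
#' different super-blocks are independent. Used to exercise the hierarchical
#' recursion of the community detector.
#'
#' @param superSizes sizes of the top-level blocks.
#' @param subBlocksPerSuper number of equal sub-blocks inside each super-block
#'   (must divide the super-block size).
#' @param rhoSuper,rhoSub correlation levels, `0 < rhoSuper < rhoSub < 1`.
#' @param nSamples,seed sampling geometry and seed.
#' @return a `SummarizedExperiment` with rowData columns `super` and `sub`.
#' @export
simulateHierarchicalCoexpression <- function(superSizes = c(150L, 150L),
                                             subBlocksPerSuper = 5L,
                                             rhoSuper = 0.4, rhoSub = 0.8,
                                             nSamples = 100L, seed = 1L) {
  stopifnot(rhoSuper > 0, rhoSub > rhoSuper, rhoSub < 1)
  if (any(superSizes %% subBlocksPerSuper != 0))
    stop("subBlocksPerSuper must divide every super-block size")
  set.seed(seed)
  nG <- sum(superSizes)
  geneIds <- sprintf("g%04d", seq_len(nG))
  sampleIds <- sprintf("s%03d", seq_len(nSamples))
  superOf <- rep(seq_along(superSizes), superSizes)
  subOf <- integer(nG)
  nextSub <- 1L
  for (s in seq_along(superSizes)) {
    sz <- superSizes[s] / subBlocksPerSuper
    subOf[superOf == s] <- rep(nextSub:(nextSub + subBlocksPerSuper - 1L),
                               each = sz)
    nextSub <- nextSub + subBlocksPerSuper
  }
  G <- matrix(rnorm(length(superSizes) * nSamples), ncol = nSamples)
  Fm <- matrix(rnorm(max(subOf) * nSamples), ncol = nSamples)
  eps <- matrix(rnorm(nG * nSamples), ncol = nSamples)
  x <- sqrt(rhoSuper) * G[superOf, , drop = FALSE] +
    sqrt(rhoSub - rhoSuper) * Fm[subOf, , drop = FALSE] +
    sqrt(1 - rhoSub) * eps
  intensity <- 2^(x + 8)
  dimnames(intensity) <- list(geneIds, sampleIds)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = intensity),
    rowData = S4Vectors::DataFrame(super = superOf, sub = subOf,
                                   row.names = geneIds),
    colData = S4Vectors::DataFrame(
      class = rep(c("case", "control"), length.out = nSamples),
      batch = rep("b1", nSamples), row.names = sampleIds),
    metadata = list(groundTruth = list(super_of_gene = setNames(superOf, geneIds),
                                       sub_of_gene = setNames(subOf, geneIds))))
}

#' Write a synthetic dataset to disk
#'
#' Writes the expression matrix (TSV, genes as rows, first column `gene_id`),
#' the sample metadata (TSV: `sample_id`, `class`, `batch`), the ground truth
#' (JSON) and, when present, the planted annotation set as a one-record GMT
#' file.
#'
#' @param se a `SummarizedExperiment` from [simulateCoexpression()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written file paths.
#' @export
writeDataset <- function(se, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  X <- .exprsOf(se)
  exprPath <- file.path(dir, "expression.tsv")
  # 17 significant digits: doubles survive the text round trip exactly
  Xtxt <- matrix(sprintf("%.17g", X), nrow(X), dimnames = dimnames(X))
  .writeTSV(data.frame(gene_id = rownames(X), Xtxt, check.names = FALSE),
            exprPath)
  metaPath <- file.path(dir, "metadata.tsv")
  .writeTSV(data.frame(sample_id = colnames(se),
                       class = as.character(SummarizedExperiment::colData(se)$class),
                       batch = as.character(SummarizedExperiment::colData(se)$batch)),
            metaPath)
  paths <- c(expression = exprPath, metadata = metaPath)
  truth <- S4Vectors::metadata(se)$groundTruth
  if (!is.null(truth)) {
    truthPath <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, truthPath, auto_unbox = FALSE, digits = NA)
    paths <- c(paths, ground_truth = truthPath)
    if (length(truth$annotation_set) > 0) {
      gmtPath <- file.path(dir, "annotation.gmt")
      writeGMT(list(planted_annotation = truth$annotation_set), gmtPath,
               description = "synthetic risk-gene set")
      paths <- c(paths, annotation = gmtPath)
    }
  }
  paths
}

#' Read an expression + metadata TSV pair into a SummarizedExperiment
#'
#' @param expressionPath TSV with first column `gene_id`, remaining columns
#'   one per sample.
#' @param metadataPath TSV with columns `sample_id`, `class`, `batch`.
#' @return a `SummarizedExperiment`.
#' @export
readDataset <- function(expressionPath, metadataPath) {
  ex <- read.delim(expressionPath, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(ex)[1] != "gene_id") stop("expression TSV must start with 'gene_id'")
  X <- as.matrix(ex[, -1, drop = FALSE])
  rownames(X) <- ex$gene_id
  if (anyDuplicated(rownames(X))) stop("duplicated gene ids")
  md <- read.delim(metadataPath, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "batch")
  if (!all(need %in% names(md)))
    stop("metadata TSV must have columns sample_id, class, batch")
  if (!setequal(md$sample_id, colnames(X)))
    stop("metadata samples do not match expression columns")
  md <- md[match(colnames(X), md$sample_id), ]
  if (anyNA(X)) stop("missing values in expression matrix")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = X),
    colData = S4Vectors::DataFrame(class = md$class, batch = md$batch,
                                   row.names = md$sample_id))
}
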