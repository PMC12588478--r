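#' Configuration of an end-to-end pipeline run
#'
#' Collects every tunable of the three-step analysis with the defaults the
#' method prescribes: edge significance 0.01, L = 100 Leiden runs per
#' configuration, stability threshold 0.80, 5% fragmentation floor, size band
#' [4, 100], 5-fold CV with 100 repetitions, a 300-tree forest with s = S,
#' the 85% accuracy screen, enrichment at the 1% (raw) and 5% (Bonferroni)
#' levels and a top-20 Shapley summary.
#'
#' @param expression,metadata paths to the expression and metadata TSVs
#'   (dialects of [writeDataset()]).
#' @param outputDir run directory (created at run time).
#' @param annotation optional GMT path for enrichment.
#' @param steps,offset preprocessing plan, see [preprocessExpression()].
#' @param alpha network edge significance level.
#' @param gammaGrid,betaGrid,L,nmiThreshold,minFraction,minSize,maxSize,maxDepth
#'   community-detection parameters, see [detectCommunities()].
#' @param nFolds,nRepetitions,rfTrees,rfMtry,borutaMaxIter,borutaTrees CV and
#'   model parameters, see [evaluateCommunity()].
#' @param accuracyThreshold screening threshold on mean CV accuracy.
#' @param enrichAlphaSingle,enrichAlphaBonferroni enrichment levels.
#' @param xaiTopK,xaiBackground Shapley summary depth and background-row cap.
#' @param baseSeed master seed of the run.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(expression, metadata, outputDir,
                           annotation = NULL,
                           steps = c("log2", "batch", "quantile"), offset = 1,
                           alpha = 0.01,
                           gammaGrid = c(0.5, 0.8, 1.0, 1.2, 1.5, 2.0),
                           betaGrid = c(0.005, 0.01, 0.05, 0.1), L = 100L,
                           nmiThreshold = 0.80, minFraction = 0.05,
                           minSize = 4L, maxSize = 100L, maxDepth = 20L,
                           nFolds = 5L, nRepetitions = 100L, rfTrees = 300L,
                           rfMtry = NULL, borutaMaxIter = 30L,
                           borutaTrees = 64L, accuracyThreshold = 0.85,
                           enrichAlphaSingle = 0.01,
                           enrichAlphaBonferroni = 0.05, xaiTopK = 20L,
                           xaiBackground = 100L, baseSeed = 1L) {
  .assertFraction(alpha, "alpha")
  .assertFraction(nmiThreshold, "nmiThreshold", lo = 0, hi = 1,
                  loOpen = FALSE, hiOpen = FALSE)
  .assertFraction(minFraction, "minFraction", lo = 0, hi = 1, loOpen = FALSE)
  .assertFraction(accuracyThreshold, "accuracyThreshold", lo = 0, hi = 1,
                  loOpen = FALSE, hiOpen = FALSE)
  if (minSize < 1 || maxSize < minSize) stop("invalid size band")
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full three-step pipeline
#'
#' preprocess -> network -> hierarchical community detection -> per-community
#' repeated-CV classification -> accuracy screen -> (optional) enrichment ->
#' Shapley attribution of the screened communities. Every stage writes its
#' artifact into the run directory and a machine-readable manifest records
#' the configuration, seed, package version and per-stage wall time; a rerun
#' with the identical configuration and seed reproduces every table
#' byte-for-byte.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the run directory, the artifact paths and
#'   the in-memory stage results.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  for (p in c(config$expression, config$metadata, config$annotation))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outputDir, ...)
  manifest <- list(package = as.character(packageVersion("coexScreen")),
                   baseSeed = config$baseSeed,
                   config = config[setdiff(names(config), "outputDir")],
                   stages = list())
  artifacts <- character(0)
  tic <- function() proc.time()[["elapsed"]]
  stageLog <- function(name, t0, ...) {
    manifest$stages[[name]] <<- c(list(seconds = round(tic() - t0, 3)),
                                  list(...))
    message(sprintf("[%s] done in %.1fs", name, tic() - t0))
  }

  t0 <- tic()
  se <- readDataset(config$expression, config$metadata)
  se <- preprocessExpression(se, steps = config$steps, offset = config$offset)
  procPath <- out("expression_preprocessed.tsv")
  .writeTSV(data.frame(gene_id = rownames(se),
                       format(.exprsOf(se), digits = 15, trim = TRUE),
                       check.names = FALSE), procPath)
  artifacts <- c(artifacts, preprocessed = procPath)
  stageLog("preprocess", t0, genes = nrow(se), samples = ncol(se))

  t0 <- tic()
  net <- buildNetwork(se, alpha = config$alpha)
  writeEdgeList(net, out("network_edges.tsv"))
  writeNetworkSummary(net, out("network_summary.json"))
  artifacts <- c(artifacts, edges = out("network_edges.tsv"),
                 network_summary = out("network_summary.json"))
  stageLog("network", t0, nodes = length(networkNodes(net)),
           edges = nrow(networkEdges(net)))

  t0 <- tic()
  cs <- withCallingHandlers(
    detectCommunities(net, minSize = config$minSize, maxSize = config$maxSize,
                      gammaGrid = config$gammaGrid, betaGrid = config$betaGrid,
                      L = config$L, baseSeed = config$baseSeed,
                      nmiThreshold = config$nmiThreshold,
                      minFraction = config$minFraction,
                      maxDepth = config$maxDepth),
    warning = function(w) {
      message("WARNING: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  writeCommunities(cs, out("communities.tsv"))
  reports <- lapply(stabilityReports(cs), function(r)
    list(gamma = r@gamma, beta = r@beta, L = r@L, mean_nmi = r@meanNMI,
         majority_frequency = r@majorityFrequency, stable = r@stable,
         substantial = r@substantial, nonfragmented = r@nonfragmented,
         retained = r@retained))
  jsonlite::write_json(reports, out("stability_reports.json"),
                       auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, communities = out("communities.tsv"),
                 stability = out("stability_reports.json"))
  finals <- finalCommunities(cs)
  stageLog("communities", t0, final = length(finals),
           discarded = nrow(discardedCommunities(cs)))

  t0 <- tic()
  perfs <- lapply(names(finals), function(id)
    evaluateCommunity(se, finals[[id]], communityId = id,
                      nFolds = config$nFolds,
                      nRepetitions = config$nRepetitions,
                      baseSeed = config$baseSeed, rfTrees = config$rfTrees,
                      rfMtry = config$rfMtry,
                      borutaMaxIter = config$borutaMaxIter,
                      borutaTrees = config$borutaTrees))
  names(perfs) <- names(finals)
  .writeTSV(performanceTable(perfs), out("performance.tsv"))
  dir.create(out("gene_frequency"), showWarnings = FALSE)
  for (id in names(perfs))
    .writeTSV(geneFrequencyTable(perfs[[id]]),
              out("gene_frequency", paste0(id, ".tsv")))
  screened <- screenCommunities(perfs, threshold = config$accuracyThreshold)
  writeLines(screened, out("screened_communities.txt"))
  artifacts <- c(artifacts, performance = out("performance.tsv"),
                 screened = out("screened_communities.txt"))
  stageLog("classification", t0, communities = length(perfs),
           screened = length(screened))

  if (!is.null(config$annotation)) {
    t0 <- tic()
    collection <- readGMT(config$annotation)
    enr <- enrichCommunities(finals, collection, networkNodes(net),
                             alphaSingle = config$enrichAlphaSingle,
                             alphaBonferroni = config$enrichAlphaBonferroni)
    .writeTSV(enr, out("enrichment.tsv"))
    artifacts <- c(artifacts, enrichment = out("enrichment.tsv"))
    stageLog("enrichment", t0, tests = nrow(enr),
             significant_raw = sum(enr$significant_raw))
  } else enr <- NULL

  t0 <- tic()
  attributions <- list()
  dir.create(out("xai"), showWarnings = FALSE)
  X <- t(.exprsOf(se))
  classes <- .classesOf(se)
  for (id in screened) {
    feats <- topGenes(perfs[[id]])
    if (length(feats) == 0) feats <- finals[[id]]
    fit <- rfTrain(X[, feats, drop = FALSE], classes, ntree = config$rfTrees,
                   mtry = config$rfMtry,
                   seed = .deriveSeed(config$baseSeed, id, "xai"))
    set.seed(.deriveSeed(config$baseSeed, id, "background"))
    bgIdx <- if (nrow(X) > config$xaiBackground)
      sort(sample.int(nrow(X), config$xaiBackground)) else seq_len(nrow(X))
    attr <- shapTree(fit, X[, feats, drop = FALSE], X[bgIdx, feats, drop = FALSE])
    summ <- summarizeAttributions(attr, topK = config$xaiTopK)
    writeAttributions(attr, out("xai", paste0(id, "_attributions.tsv")))
    .writeTSV(summ$summary, out("xai", paste0(id, "_summary.tsv")))
    attributions[[id]] <- attr
  }
  stageLog("xai", t0, explained = length(attributions))

  manifest$artifacts <- as.list(artifacts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(outputDir = config$outputDir, artifacts = artifacts,
                 network = net, communities = cs, performances = perfs,
                 screened = screened, enrichment = enr,
                 attributions = attributions))
}

#' Generate and write a synthetic dataset in one call
#'
#' Thin wrapper over [simulateCoexpression()] + [writeDataset()] — the
#' "simulate" entry point of the pipeline.
#'
#' @param config a [syntheticConfig()] (or a list of its arguments).
#' @param dir output directory.
#' @return named character vector of written paths.
#' @export
simulateDataset <- function(config, dir) {
  if (!inherits(config, "SyntheticConfig"))
    config <- do.call(syntheticConfig, as.list(config))
  writeDataset(simulateCoexpression(config), dir)
}
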