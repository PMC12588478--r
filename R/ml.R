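#' Stratified cross-validation folds
#'
#' Splits samples into `nFolds` disjoint test sets covering everything, with
#' class proportions preserved to within one sample per fold. Deterministic
#' given (`baseSeed`, `repetition`).
#'
#' @param classes named character vector (`"case"`/`"control"` per sample).
#' @param nFolds number of folds (default 5; each class needs >= nFolds
#'   members).
#' @param baseSeed integer seed.
#' @param repetition repetition index (different repetitions reshuffle).
#' @return list of `nFolds` elements, each `list(train = ids, test = ids)`.
#' @export
stratifiedFolds <- function(classes, nFolds = 5L, baseSeed = 1L,
                            repetition = 1L) {
  if (is.null(names(classes))) stop("classes must be named by sample id")
  tab <- table(factor(classes, levels = c("case", "control")))
  if (any(tab < nFolds))
    stop(sprintf("class '%s' has %d samples; >= %d required",
                 names(tab)[which.min(tab)], min(tab), nFolds))
  set.seed(.deriveSeed(baseSeed, "folds", repetition))
  fold <- setNames(integer(length(classes)), names(classes))
  for (cl in c("case", "control")) {
    ids <- sample(names(classes)[classes == cl])
    fold[ids] <- rep_len(seq_len(nFolds), length(ids))
  }
  lapply(seq_len(nFolds), function(f)
    list(train = names(fold)[fold != f], test = names(fold)[fold == f]))
}

# rank-based (Mann-Whitney) AUC of case-probability scores
.aucScore <- function(scores, labels) {
  pos <- labels == "case"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

# F1 with "case" as the positive class; 0 when the denominator vanishes
.f1Score <- function(pred, truth) {
  tp <- sum(pred == "case" & truth == "case")
  fp <- sum(pred == "case" & truth == "control")
  fn <- sum(pred == "control" & truth == "case")
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den
}

#' Cross-validated classification of one gene community
#'
#' The core screening unit: for every repetition x fold, Boruta runs on the
#' TRAINING split restricted to the community's genes, a Random Forest
#' (default M = 300 trees, s = S features per split) is trained on the
#' confirmed genes — falling back to all community genes when Boruta confirms
#' nothing, so no fold is discarded — and accuracy, AUC and F1 are scored on
#' the held-out fold. Metrics are aggregated as the mean and SD of the
#' repetition-level means. Selection counts per gene and the average
#' confirmed count N yield the top-N gene list (ranked by frequency, ties by
#' mean importance, then gene id). Test rows never influence selection or
#' training.
#'
#' @param se preprocessed `SummarizedExperiment` (genes x samples) whose
#'   colData has a `class` column.
#' @param genes the community's genes (must be present in `se`).
#' @param communityId identifier stored in the result.
#' @param nFolds,nRepetitions CV geometry (defaults 5 and 100).
#' @param baseSeed seed from which every fold, Boruta run and forest derives
#'   its own stream.
#' @param rfTrees,rfMtry classification forest size and features per split
#'   (`NULL` = all, i.e. s = S).
#' @param borutaMaxIter,borutaTrees,borutaMtry selector settings, see
#'   [borutaSelect()].
#' @return a [CommunityPerformance-class].
#' @export
evaluateCommunity <- function(se, genes, communityId = "community",
                              nFolds = 5L, nRepetitions = 100L,
                              baseSeed = 1L, rfTrees = 300L, rfMtry = NULL,
                              borutaMaxIter = 30L, borutaTrees = 64L,
                              borutaMtry = "sqrt") {
  if (length(genes) == 0) stop("empty community")
  X <- .exprsOf(se)
  missing <- setdiff(genes, rownames(X))
  if (length(missing) > 0)
    stop("community gene(s) absent from the matrix: ",
         paste(head(missing, 5), collapse = ", "))
  Xc <- t(X[genes, , drop = FALSE])
  classes <- .classesOf(se)

  nSel <- c(); freq <- setNames(rep(0L, length(genes)), genes)
  impSum <- setNames(rep(0, length(genes)), genes)
  impN <- setNames(rep(0L, length(genes)), genes)
  repAcc <- repAuc <- repF1 <- numeric(nRepetitions)

  for (rep_ in seq_len(nRepetitions)) {
    folds <- stratifiedFolds(classes, nFolds = nFolds, baseSeed = baseSeed,
                             repetition = rep_)
    acc <- auc <- f1 <- numeric(nFolds)
    for (f in seq_len(nFolds)) {
      tr <- folds[[f]]$train; te <- folds[[f]]$test
      bs <- borutaSelect(Xc[tr, , drop = FALSE], classes[tr],
                         seed = .deriveSeed(baseSeed, communityId, rep_, f),
                         maxIter = borutaMaxIter, ntree = borutaTrees,
                         mtry = borutaMtry)
      nSel <- c(nSel, length(bs$confirmed))
      freq[bs$confirmed] <- freq[bs$confirmed] + 1L
      present <- names(impN)  # importance observed for every community gene
      impSum[present] <- impSum[present] + bs$importance[present]
      impN[present] <- impN[present] + 1L
      sel <- if (length(bs$confirmed) > 0) bs$confirmed else genes
      fit <- rfTrain(Xc[tr, sel, drop = FALSE], classes[tr], ntree = rfTrees,
                     mtry = rfMtry,
                     seed = .deriveSeed(baseSeed, communityId, rep_, f, "rf"))
      prob <- predict(fit, Xc[te, sel, drop = FALSE], type = "prob")
      pred <- ifelse(prob > 0.5, "case", "control")
      acc[f] <- mean(pred == classes[te])
      auc[f] <- .aucScore(prob, classes[te])
      f1[f] <- .f1Score(pred, classes[te])
    }
    repAcc[rep_] <- mean(acc); repAuc[rep_] <- mean(auc); repF1[rep_] <- mean(f1)
  }

  N <- mean(nSel)
  meanImp <- ifelse(impN > 0, impSum / pmax(impN, 1L), 0)
  ord <- order(-freq, -meanImp, names(freq))
  top <- names(freq)[ord][seq_len(round(N))]
  sdOr0 <- function(v) if (length(v) > 1) sd(v) else 0
  new("CommunityPerformance", communityId = communityId, genes = genes,
      metrics = c(accuracy_mean = mean(repAcc), accuracy_sd = sdOr0(repAcc),
                  auc_mean = mean(repAuc), auc_sd = sdOr0(repAuc),
                  f1_mean = mean(repF1), f1_sd = sdOr0(repF1)),
      borutaAvgSelected = N,
      geneFrequency = setNames(as.numeric(freq), names(freq)),
      geneImportance = setNames(as.numeric(meanImp), names(meanImp)),
      topGenes = top, nFolds = as.integer(nFolds),
      nRepetitions = as.integer(nRepetitions))
}

#' Validate a community on an independent dataset
#'
#' Runs the identical repeated-CV procedure on a second dataset restricted to
#' the community's genes that are present there. Requires at least
#' `minOverlap` of the genes to be matched; missing genes are reported.
#'
#' @param se the independent `SummarizedExperiment`.
#' @param genes the community's gene set (from the training analysis).
#' @param minOverlap minimum matched fraction (default 0.5).
#' @param ... passed on to [evaluateCommunity()].
#' @inheritParams evaluateCommunity
#' @return a [CommunityPerformance-class] on the matched genes.
#' @export
validateOnIndependent <- function(se, genes, communityId = "community",
                                  minOverlap = 0.5, ...) {
  matched <- intersect(genes, rownames(.exprsOf(se)))
  missing <- setdiff(genes, matched)
  if (length(matched) < minOverlap * length(genes) || length(matched) == 0)
    stop(sprintf("only %d/%d community genes present in the independent set; missing: %s",
                 length(matched), length(genes),
                 paste(head(missing, 10), collapse = ", ")))
  if (length(missing) > 0)
    message(sprintf("%d gene(s) not in the independent set: %s",
                    length(missing), paste(missing, collapse = ", ")))
  evaluateCommunity(se, matched, communityId = communityId, ...)
}

#' Screen communities by mean CV accuracy
#'
#' @param performances list of [CommunityPerformance-class] objects.
#' @param threshold retain communities with `accuracy_mean` strictly above
#'   this value (default 0.85).
#' @return character vector of retained community ids, sorted by descending
#'   accuracy (ties by community id).
#' @export
screenCommunities <- function(performances, threshold = 0.85) {
  if (length(performances) == 0) stop("no performances supplied")
  ids <- vapply(performances, function(p) p@communityId, character(1))
  acc <- vapply(performances, function(p)
    unname(p@metrics["accuracy_mean"]), numeric(1))
  keep <- acc > threshold
  ids[keep][order(-acc[keep], ids[keep])]
}

#' Tabulate community performances for export
#'
#' @param performances list of `CommunityPerformance` objects.
#' @return data.frame with one row per community (the performance TSV
#'   dialect).
#' @export
performanceTable <- function(performances) {
  do.call(rbind, lapply(performances, function(p) {
    m <- p@metrics
    data.frame(community_id = p@communityId, n_genes = length(p@genes),
               accuracy_mean = m[["accuracy_mean"]],
               accuracy_sd = m[["accuracy_sd"]],
               auc_mean = m[["auc_mean"]], auc_sd = m[["auc_sd"]],
               f1_mean = m[["f1_mean"]], f1_sd = m[["f1_sd"]],
               boruta_avg_selected = p@borutaAvgSelected,
               stringsAsFactors = FALSE)
  }))
}

#' Per-gene selection table of one community
#'
#' @param performance a `CommunityPerformance`.
#' @return data.frame: gene_id, selection_count, mean_importance, in_top_n.
#' @export
geneFrequencyTable <- function(performance) {
  g <- names(performance@geneFrequency)
  data.frame(gene_id = g,
             selection_count = as.integer(performance@geneFrequency),
             mean_importance = as.numeric(performance@geneImportance[g]),
             in_top_n = as.integer(g %in% performance@topGenes),
             stringsAsFactors = FALSE)
}
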