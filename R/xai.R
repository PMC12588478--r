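#' Exact Shapley values by subset enumeration
#'
#' The brute-force reference: for a black-box scoring function f and a
#' feature vector x, the attribution of feature j is the weighted sum
#' `sum over F subsets of S \ {j} of |F|! (|S|-|F|-1)! / |S|! *
#' (f_x(F + j) - f_x(F))`, where `f_x(F)` is the model's expected output with
#' the features outside F replaced by background values (interventional
#' averaging over the background rows). Enumeration over all 2^|S| subsets
#' bounds |S| at 12.
#'
#' @param predictFun function taking a numeric matrix (rows = inputs, columns
#'   named like `x`) and returning a numeric score per row.
#' @param x named numeric feature vector (the observation to explain).
#' @param background matrix of reference rows (columns matching `x`).
#' @param maxFeatures enumeration bound (default 12).
#' @return list with `phi` (named attributions), `baseValue` (`f_x` of the
#'   empty set) and `fx` (model output at `x`).
#' @export
shapExact <- function(predictFun, x, background, maxFeatures = 12L) {
  p <- length(x)
  if (p > maxFeatures)
    stop(sprintf("%d features exceeds the exact enumeration bound (%d); use shapTree() for larger models",
                 p, maxFeatures))
  if (is.null(names(x))) names(x) <- colnames(background)
  background <- as.matrix(background[, names(x), drop = FALSE])
  nMask <- bitwShiftL(1L, p)
  v <- numeric(nMask)
  for (mask in 0:(nMask - 1L)) {
    M <- background
    for (j in seq_len(p))
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) M[, j] <- x[[j]]
    v[mask + 1L] <- mean(predictFun(M))
  }
  popcount <- vapply(0:(nMask - 1L), function(m) sum(
    bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L), numeric(1))
  w <- factorial(0:(p - 1L)) * factorial(p - (0:(p - 1L)) - 1L) / factorial(p)
  phi <- setNames(numeric(p), names(x))
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(nMask - 1L), bit) == 0L) - 1L
    phi[j] <- sum(w[popcount[without + 1L] + 1L] *
                    (v[bitwOr(without, bit) + 1L] - v[without + 1L]))
  }
  list(phi = phi, baseValue = v[1], fx = v[nMask])
}

#' Interventional tree-Shapley attribution of a Random Forest
#'
#' Polynomial-time exact Shapley values for the forest's vote-fraction
#' output, under interventional background averaging: for every background
#' row the restriction of a tree to a feature coalition is a multilinear
#' product game over the leaf path constraints, whose Shapley values have a
#' closed form; summing over leaves, trees and background rows reproduces
#' [shapExact()] (same background) to numerical precision while scaling to
#' full-size models. Satisfies local accuracy on every explained sample:
#' `baseValue + rowSums(phi) = f(x)`.
#'
#' @param model an `rfForest` from [rfTrain()].
#' @param X samples x features matrix to explain (columns must cover the
#'   model's features).
#' @param background reference matrix; conventionally a seeded subsample of
#'   the training split capped at ~100 rows.
#' @return an [AttributionMatrix-class].
#' @export
shapTree <- function(model, X, background) {
  stopifnot(inherits(model, "rfForest"))
  miss <- setdiff(model$featureNames, colnames(X))
  if (length(miss) > 0)
    stop("X lacks model feature(s): ", paste(miss, collapse = ", "))
  missB <- setdiff(model$featureNames, colnames(background))
  if (length(missB) > 0)
    stop("background lacks model feature(s): ", paste(missB, collapse = ", "))
  Xo <- as.matrix(X[, model$featureNames, drop = FALSE])
  Bo <- as.matrix(background[, model$featureNames, drop = FALSE])
  res <- .shap_interventional_cpp(model$trees, Xo, Bo)
  phi <- res$phi
  dimnames(phi) <- dimnames(Xo)
  out <- predict(model, Xo, type = "prob")
  new("AttributionMatrix", values = phi, baseValue = res$base,
      modelOutput = as.numeric(out), featureValues = Xo)
}

#' Summarize an attribution matrix
#'
#' Features are ranked by mean |phi| (descending, ties by feature id); the
#' direction summary is the sign of the correlation between a feature's
#' values and its Shapley values (negative means low values push towards a
#' case call, as in the beeswarm reading of summary plots).
#'
#' @param attr an `AttributionMatrix`.
#' @param topK number of top features to export (default 20; clamped to the
#'   feature count).
#' @return list with `summary` (gene_id, mean_abs_shap, rank, direction) and
#'   `points` (long table of per-sample (phi, value) pairs for the topK
#'   features, for beeswarm-style plotting).
#' @export
summarizeAttributions <- function(attr, topK = 20L) {
  V <- attr@values
  if (ncol(V) == 0) stop("empty attribution")
  meanAbs <- colMeans(abs(V))
  ord <- order(-meanAbs, colnames(V))
  direction <- vapply(seq_len(ncol(V)), function(j) {
    fv <- attr@featureValues[, j]
    if (sd(fv) == 0 || sd(V[, j]) == 0) return(0)
    sign(cor(fv, V[, j]))
  }, numeric(1))
  summary <- data.frame(gene_id = colnames(V)[ord],
                        mean_abs_shap = meanAbs[ord],
                        rank = seq_along(ord),
                        direction = direction[ord],
                        stringsAsFactors = FALSE, row.names = NULL)
  k <- min(topK, ncol(V))
  topFeat <- summary$gene_id[seq_len(k)]
  samples <- rownames(V)
  if (is.null(samples)) samples <- sprintf("sample%03d", seq_len(nrow(V)))
  points <- do.call(rbind, lapply(topFeat, function(g)
    data.frame(gene_id = g, sample_id = samples,
               shap_value = V[, g], feature_value = attr@featureValues[, g],
               stringsAsFactors = FALSE, row.names = NULL)))
  list(summary = summary, points = points)
}

#' Write the long-format attribution TSV
#' @param attr an `AttributionMatrix`
#' @param path output path
#' @return the path, invisibly
#' @export
writeAttributions <- function(attr, path) {
  V <- attr@values
  samples <- rownames(V)
  if (is.null(samples)) samples <- sprintf("sample%03d", seq_len(nrow(V)))
  long <- do.call(rbind, lapply(colnames(V), function(g)
    data.frame(sample_id = samples, gene_id = g, shap_value = V[, g],
               feature_value = attr@featureValues[, g],
               stringsAsFactors = FALSE, row.names = NULL)))
  .writeTSV(long, path)
}
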