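#' Log2-transform an expression matrix
#'
#' @param se `SummarizedExperiment` or matrix of intensities.
#' @param offset nonnegative value added before taking log2 (default 1, so
#'   intensities near zero stay finite).
#' @return object of the same type with `log2(value + offset)` values.
#' @export
log2Transform <- function(se, offset = 1) {
  if (offset < 0) stop("offset must be nonnegative")
  X <- .exprsOf(se)
  bad <- which(X + offset <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("nonpositive value after offset at gene '%s', sample '%s'",
                 rownames(X)[bad[1, 1]], colnames(X)[bad[1, 2]]))
  Y <- log2(X + offset)
  .replaceExprs(se, Y)
}

.replaceExprs <- function(se, Y) {
  if (is(se, "SummarizedExperiment")) {
    SummarizedExperiment::assay(se) <- Y
    se
  } else Y
}

#' Quantile-normalize sample columns
#'
#' Forces every sample to the same value distribution: the across-sample mean
#' of order statistics. Within-column ranks are preserved; tied values receive
#' the mean of the reference values at their tied ranks. On tie-free data the
#' operation is exactly idempotent.
#'
#' @param se `SummarizedExperiment` or genes x samples matrix (>= 2 samples).
#' @return the normalized object.
#' @export
quantileNormalize <- function(se) {
  X <- .exprsOf(se)
  if (ncol(X) < 2) stop("quantile normalization needs at least 2 samples")
  ref <- rowMeans(apply(X, 2, sort, method = "radix"))
  Y <- apply(X, 2, function(col) {
    o <- order(col)
    sorted <- col[o]
    grp <- cumsum(c(1L, as.integer(diff(sorted) != 0)))
    groupMeans <- vapply(split(ref, grp), mean, numeric(1))
    out <- numeric(length(col))
    out[o] <- groupMeans[grp]
    out
  })
  dimnames(Y) <- dimnames(X)
  .replaceExprs(se, Y)
}

#' Controls-anchored per-gene batch adjustment
#'
#' For every (gene, batch) a location and a scale coefficient are estimated
#' from that batch's CONTROL samples only (batch control mean and SD versus
#' the pooled control mean and SD across all batches); the affine correction
#' `(x - m_batch) * s_pooled / s_batch + m_pooled` is then applied to every
#' sample of the batch, case and control alike. Case samples never influence
#' the coefficients. A degenerate control SD (< 1e-12) in a batch, or a
#' degenerate pooled SD, sets the scale factor to 1 for that gene/batch.
#'
#' @param se `SummarizedExperiment` whose `colData` has `class` and `batch`;
#'   every batch must contain at least 2 control samples.
#' @return the adjusted `SummarizedExperiment`.
#' @export
batchAdjustOnControls <- function(se) {
  X <- .exprsOf(se)
  classes <- .classesOf(se)
  batches <- .batchesOf(se)
  ub <- unique(batches)
  if (length(ub) == 1) return(se)
  for (b in ub) {
    nCtl <- sum(batches == b & classes == "control")
    if (nCtl < 2)
      stop(sprintf("batch '%s' has %d control samples; >= 2 required", b, nCtl))
  }
  ctl <- classes == "control"
  mPool <- rowMeans(X[, ctl, drop = FALSE])
  sPool <- apply(X[, ctl, drop = FALSE], 1, sd)
  Y <- X
  for (b in ub) {
    inB <- batches == b
    ctlB <- inB & ctl
    mB <- rowMeans(X[, ctlB, drop = FALSE])
    sB <- apply(X[, ctlB, drop = FALSE], 1, sd)
    scale <- ifelse(sB < 1e-12 | sPool < 1e-12, 1, sPool / sB)
    Y[, inB] <- (X[, inB, drop = FALSE] - mB) * scale + mPool
  }
  .replaceExprs(se, Y)
}

#' Run the full preprocessing pipeline
#'
#' Default order is log2, then batch adjust, then quantile normalization:
#' the location-scale batch correction acts on the (roughly symmetric) log
#' scale, where additive/multiplicative batch artifacts live; applied to raw
#' skewed intensities it can produce negative values. The order is
#' configurable because the field has no single convention for where batch
#' correction sits relative to the transform steps.
#'
#' @param se `SummarizedExperiment` of raw intensities.
#' @param steps character vector, an ordering of a subset of
#'   `c("batch", "log2", "quantile")`.
#' @param offset log2 offset.
#' @return the preprocessed `SummarizedExperiment`.
#' @export
preprocessExpression <- function(se, steps = c("log2", "batch", "quantile"),
                                 offset = 1) {
  unknown <- setdiff(steps, c("batch", "log2", "quantile"))
  if (length(unknown) > 0)
    stop("unknown preprocessing step: ", paste(unknown, collapse = ", "))
  for (s in steps) {
    se <- switch(s,
                 batch = batchAdjustOnControls(se),
                 log2 = log2Transform(se, offset = offset),
                 quantile = quantileNormalize(se))
  }
  se
}
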