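#' Boruta shadow-feature selection
#'
#' Wrapper feature selection against a permutation null: at every iteration
#' each remaining feature is shuffled into a "shadow" copy, a Random Forest
#' is trained on the real + shadow columns, and a feature scores a *hit* when
#' its Gini importance exceeds the best shadow importance. Hits accumulate
#' across iterations and each still-undecided feature is tested two-sided
#' against Binomial(iterations, 1/2) with Bonferroni correction over the
#' original feature count: significantly many hits confirms the feature,
#' significantly few rejects it (rejected features leave the model). The loop
#' stops when nothing is left undecided or `maxIter` is reached; features
#' still tentative at the end are conservatively not confirmed.
#'
#' @param x samples x features matrix with column names (training split).
#' @param y `"case"`/`"control"` labels, >= 2 samples per class.
#' @param seed integer seed; the run is fully deterministic given it.
#' @param maxIter maximum number of shadow iterations.
#' @param ntree trees of the internal forest per iteration.
#' @param mtry features per split for the internal forest; defaults to the
#'   square-root rule over real + shadow columns (the selector's standard),
#'   independent of the classification forest's s = S setting.
#' @param alpha significance level of the binomial decisions.
#' @param minIter first iteration at which decisions are attempted.
#' @return list with `confirmed`, `tentative`, `rejected` (character),
#'   `importance` (named mean importance over the iterations in which each
#'   feature was present), `hits`, and `nIter`.
#' @export
borutaSelect <- function(x, y, seed = 1L, maxIter = 30L, ntree = 64L,
                         mtry = "sqrt", alpha = 0.05, minIter = 5L) {
  if (!is.matrix(x) || is.null(colnames(x)))
    stop("x must be a matrix with column names")
  y <- as.character(y)
  if (min(table(factor(y, levels = c("case", "control")))) < 2)
    stop("degenerate training split: need >= 2 samples per class")
  genes <- colnames(x)
  p0 <- length(genes)
  status <- setNames(rep(0L, p0), genes)  # 0 tentative, 1 confirmed, -1 rejected
  hits <- setNames(rep(0L, p0), genes)
  impSum <- setNames(rep(0, p0), genes)
  impN <- setNames(rep(0L, p0), genes)
  set.seed(as.integer(seed))
  iter <- 0L
  while (any(status == 0L) && iter < maxIter) {
    iter <- iter + 1L
    active <- names(status)[status >= 0L]
    xa <- x[, active, drop = FALSE]
    shadows <- apply(xa, 2, sample)
    colnames(shadows) <- paste0(".shadow.", active)
    rownames(shadows) <- rownames(xa)
    xFull <- cbind(xa, shadows)
    m <- if (identical(mtry, "sqrt")) max(1L, floor(sqrt(ncol(xFull))))
    else as.integer(mtry)
    fit <- rfTrain(xFull, y, ntree = ntree, mtry = m,
                   seed = sample.int(.seedCap, 1))
    imp <- rfImportance(fit)
    maxShadow <- max(imp[colnames(shadows)])
    impSum[active] <- impSum[active] + imp[active]
    impN[active] <- impN[active] + 1L
    tent <- names(status)[status == 0L]
    hits[tent] <- hits[tent] + as.integer(imp[tent] > maxShadow)
    if (iter >= minIter) {
      cut <- alpha / p0
      pUp <- pbinom(hits[tent] - 1, iter, 0.5, lower.tail = FALSE)
      pDn <- pbinom(hits[tent], iter, 0.5)
      status[tent[pUp < cut]] <- 1L
      status[tent[pDn < cut]] <- -1L
    }
  }
  meanImp <- ifelse(impN > 0, impSum / pmax(impN, 1L), 0)
  list(confirmed = genes[status == 1L],
       tentative = genes[status == 0L],
       rejected = genes[status == -1L],
       importance = setNames(as.numeric(meanImp), genes),
       hits = hits, nIter = iter)
}
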