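#' Train a Random Forest case/control classifier
#'
#' A compact CART/Gini forest: each tree is grown on a bootstrap sample of
#' the rows, considering `mtry` randomly drawn features per split. Following
#' the analysis convention this package implements, the default `mtry` is the
#' FULL feature count (s = S); the conventional square-root rule is available
#' via `mtry = "sqrt"`. Prediction scores are tree-vote fractions: the share
#' of trees whose reached leaf has a case majority (an exactly tied leaf
#' votes control). Training is deterministic given `seed`, independently of
#' R's RNG state.
#'
#' @param x samples x features numeric matrix with column names.
#' @param y class labels, values `"case"` / `"control"` (case is positive).
#' @param ntree number of trees M (default 300).
#' @param mtry features considered per split: `NULL` for all (s = S),
#'   `"sqrt"` for the square-root rule, or an integer.
#' @param minSplit minimum node size eligible for splitting.
#' @param maxDepth maximum tree depth.
#' @param seed integer seed.
#' @return an object of class `rfForest`.
#' @export
rfTrain <- function(x, y, ntree = 300L, mtry = NULL, minSplit = 2L,
                    maxDepth = 25L, seed = 1L) {
  if (!is.matrix(x) || is.null(colnames(x)))
    stop("x must be a matrix with column names")
  y <- as.character(y)
  if (!all(y %in% c("case", "control")))
    stop("y must contain only 'case' and 'control'")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  p <- ncol(x)
  m <- if (is.null(mtry)) p
  else if (identical(mtry, "sqrt")) max(1L, floor(sqrt(p)))
  else as.integer(mtry)
  if (m < 1 || m > p) stop("mtry must lie in [1, ncol(x)]")
  fit <- .rf_train_cpp(x, as.integer(y == "case"), as.integer(ntree),
                       as.integer(m), as.integer(minSplit),
                       as.integer(maxDepth), as.numeric(seed))
  structure(list(trees = fit$trees,
                 importance = setNames(as.numeric(fit$importance), colnames(x)),
                 featureNames = colnames(x), ntree = as.integer(ntree),
                 mtry = m), class = "rfForest")
}

#' @export
predict.rfForest <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(colnames(newdata)) ||
      !all(object$featureNames %in% colnames(newdata)))
    stop("newdata lacks feature column(s): ",
         paste(setdiff(object$featureNames, colnames(newdata)), collapse = ", "))
  nd <- as.matrix(newdata[, object$featureNames, drop = FALSE])
  prob <- as.numeric(.rf_predict_cpp(object$trees, nd))
  names(prob) <- rownames(nd)
  if (type == "prob") prob else
    setNames(ifelse(prob > 0.5, "case", "control"), rownames(nd))
}

#' Gini importance of a fitted forest
#'
#' Mean (over trees) weighted impurity decrease attributable to each feature.
#'
#' @param model an `rfForest`.
#' @return named numeric vector.
#' @export
rfImportance <- function(model) {
  stopifnot(inherits(model, "rfForest"))
  model$importance
}

#' @export
print.rfForest <- function(x, ...) {
  cat(sprintf("rfForest: %d trees, %d features, mtry=%d\n",
              x$ntree, length(x$featureNames), x$mtry))
  invisible(x)
}
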