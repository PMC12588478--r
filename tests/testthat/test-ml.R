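test_that("stratified folds preserve class balance and are deterministic", {
  classes <- setNames(rep(c("case", "control"), each = 10),
                      sprintf("s%02d", 1:20))
  folds <- stratifiedFolds(classes, nFolds = 5, baseSeed = 1, repetition = 1)
  tests <- lapply(folds, `[[`, "test")
  for (te in tests) {
    expect_identical(sum(classes[te] == "case"), 2L)
    expect_identical(sum(classes[te] == "control"), 2L)
  }
  expect_setequal(unlist(tests), names(classes))
  expect_identical(sum(lengths(tests)), 20L)
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(tests[[i]], tests[[j]]), 0)
  expect_identical(folds,
                   stratifiedFolds(classes, 5, baseSeed = 1, repetition = 1))
  expect_false(identical(folds,
                         stratifiedFolds(classes, 5, baseSeed = 1, repetition = 2)))
  expect_error(stratifiedFolds(setNames(c(rep("case", 3), rep("control", 9)),
                                        sprintf("s%02d", 1:12)), nFolds = 5),
               "case")
})

test_that("the forest is deterministic, separable and importance-coherent", {
  set.seed(10)
  x <- matrix(rnorm(600), 150, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- ifelse(x[, 2] > 0, "case", "control")
  fit <- rfTrain(x, y, ntree = 60, seed = 4)
  expect_identical(fit$trees, rfTrain(x, y, ntree = 60, seed = 4)$trees)
  prob <- predict(fit, x)
  expect_gte(mean((prob > 0.5) == (y == "case")), 0.98)
  imp <- rfImportance(fit)
  expect_identical(names(which.max(imp)), "f2")
  expect_identical(unname(predict(fit, x, type = "class")),
                   unname(ifelse(prob > 0.5, "case", "control")))
  expect_error(rfTrain(x, y, mtry = 9), "mtry")
  expect_error(rfTrain(x, rep("yes", 150)), "case")
  expect_error(predict(fit, x[, 1:2]), "f3")
})

test_that("Boruta confirms a perfectly informative gene and rejects noise", {
  set.seed(20)
  x <- matrix(rnorm(1500), 100, 15,
              dimnames = list(NULL, sprintf("g%02d", 1:15)))
  y <- ifelse(x[, 7] > 0, "case", "control")
  bs <- borutaSelect(x, y, seed = 2)
  expect_true("g07" %in% bs$confirmed)
  expect_gte(length(bs$rejected), 10)
  expect_identical(names(which.max(bs$importance)), "g07")

  yNoise <- sample(y)
  bs0 <- borutaSelect(x, yNoise, seed = 2)
  expect_lte(length(bs0$confirmed), 1)
  expect_error(borutaSelect(x[1:3, ], y[1:3], seed = 1), "degenerate")
})

test_that("community evaluation is deterministic and nails a separable signal", {
  set.seed(30)
  X <- matrix(rnorm(8 * 60), 8, 60,
              dimnames = list(sprintf("g%02d", 1:8), sprintf("s%02d", 1:60)))
  classes <- ifelse(X[3, ] > 0, "case", "control")
  se <- makeSE(X, classes = classes)
  p1 <- evaluateCommunity(se, rownames(X), "c1", nRepetitions = 2, baseSeed = 9)
  expect_gte(performanceMetrics(p1)[["accuracy_mean"]], 0.9)
  expect_true("g03" %in% topGenes(p1))
  p2 <- evaluateCommunity(se, rownames(X), "c1", nRepetitions = 2, baseSeed = 9)
  expect_identical(performanceMetrics(p1), performanceMetrics(p2))
  expect_identical(geneSelectionFrequency(p1), geneSelectionFrequency(p2))
  expect_error(evaluateCommunity(se, character(0)), "empty")
  expect_error(evaluateCommunity(se, c("g01", "nope")), "nope")
})

test_that("feature selection and training never touch the test folds", {
  set.seed(40)
  X <- matrix(rnorm(10 * 80), 10, 80,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:80)))
  classes <- setNames(ifelse(X[1, ] + rnorm(80, sd = 0.5) > 0,
                             "case", "control"), colnames(X))
  se <- makeSE(X, classes = classes)
  # corrupt exactly the held-out block of one fold: the selection and the
  # model fitted on the training block must not move
  folds <- stratifiedFolds(classes, nFolds = 5, baseSeed = 3, repetition = 1)
  tr <- folds[[1]]$train
  bsClean <- borutaSelect(t(X[, tr]), classes[tr], seed = 11)
  Xc2 <- X; Xc2[, folds[[1]]$test] <- 999
  bsCorrupt <- borutaSelect(t(Xc2[, tr]), classes[tr], seed = 11)
  expect_identical(bsClean$confirmed, bsCorrupt$confirmed)
  expect_identical(bsClean$importance, bsCorrupt$importance)

  fitClean <- rfTrain(t(X[, tr]), classes[tr], ntree = 30, seed = 5)
  fitCorrupt <- rfTrain(t(Xc2[, tr]), classes[tr], ntree = 30, seed = 5)
  expect_identical(predict(fitClean, t(X[, tr])),
                   predict(fitCorrupt, t(X[, tr])))
})

test_that("independent validation enforces the gene-overlap contract", {
  set.seed(50)
  X <- matrix(rnorm(6 * 60), 6, 60,
              dimnames = list(sprintf("g%02d", 1:6), sprintf("s%02d", 1:60)))
  classes <- ifelse(X[1, ] > 0, "case", "control")
  se <- makeSE(X, classes = classes)
  expect_error(validateOnIndependent(se, c("x1", "x2", "x3")), "0/3")
  expect_error(validateOnIndependent(se, c("g01", "x1", "x2"), minOverlap = 0.5),
               "1/3")
  expect_message(
    perf <- validateOnIndependent(se, c("g01", "g02", "g03", "x9"),
                                  minOverlap = 0.5, nRepetitions = 1,
                                  baseSeed = 2),
    "x9")
  expect_gte(performanceMetrics(perf)[["accuracy_mean"]], 0.9)
})

test_that("screening ranks by accuracy with deterministic ties", {
  mk <- function(id, acc) methods::new(
    "CommunityPerformance", communityId = id, genes = c("a", "b"),
    metrics = c(accuracy_mean = acc, accuracy_sd = 0, auc_mean = acc,
                auc_sd = 0, f1_mean = acc, f1_sd = 0),
    borutaAvgSelected = 1, geneFrequency = c(a = 1, b = 0),
    geneImportance = c(a = 1, b = 0), topGenes = "a", nFolds = 5L,
    nRepetitions = 1L)
  ps <- list(mk("cB", 0.9), mk("cA", 0.9), mk("cC", 0.5), mk("cD", 0.99))
  expect_identical(screenCommunities(ps, 0.85), c("cD", "cA", "cB"))
  expect_identical(screenCommunities(ps, 0), c("cD", "cA", "cB", "cC"))
  expect_identical(screenCommunities(ps, 1.01), character(0))
  expect_error(screenCommunities(list()), "no performances")
  tab <- performanceTable(ps)
  expect_identical(tab$community_id, c("cB", "cA", "cC", "cD"))
  expect_named(geneFrequencyTable(ps[[1]]),
               c("gene_id", "selection_count", "mean_importance", "in_top_n"))
})
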