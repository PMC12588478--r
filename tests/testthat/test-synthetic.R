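test_that("config validation names the offending field", {
  expect_error(syntheticConfig(nCase = 100, nSamples = 100), "nCase")
  expect_error(syntheticConfig(moduleSizes = rep(100L, 5), nGenes = 300),
               "moduleSizes")
  expect_error(syntheticConfig(informativeFraction = 0), "informativeFraction")
  expect_error(syntheticConfig(withinModuleCor = 1), "withinModuleCor")
  expect_error(syntheticConfig(annotationSize = 5, annotationOverlap = 8),
               "annotationOverlap")
  expect_error(syntheticConfig(nGenes = 0), "nGenes")
})

test_that("generator is deterministic and matches its stated construction", {
  cfg <- syntheticConfig(nGenes = 120L, nSamples = 200L, nCase = 100L,
                         moduleSizes = rep(20L, 3), withinModuleCor = 0.9,
                         discriminativeModules = integer(0), effectSize = 0,
                         annotationSize = 1L, annotationOverlap = 0L,
                         seed = 7)
  se1 <- simulateCoexpression(cfg)
  se2 <- simulateCoexpression(cfg)
  expect_identical(SummarizedExperiment::assay(se1),
                   SummarizedExperiment::assay(se2))

  X <- log2(SummarizedExperiment::assay(se1))
  truth <- S4Vectors::metadata(se1)$groundTruth
  mod <- truth$module_of_gene
  # mean pairwise within-module correlation ~ rho (+/- 0.05 at n = 200)
  for (m in 1:3) {
    C <- cor(t(X[names(mod)[mod == m], ]))
    expect_equal(mean(C[upper.tri(C)]), 0.9, tolerance = 0.06)
  }
  # with no planted effect, no gene separates the classes beyond noise
  classes <- truth$class_of_sample
  tstats <- apply(X, 1, function(v)
    t.test(v[classes == "case"], v[classes == "control"])$statistic)
  expect_lt(max(abs(tstats)), 5)
})

test_that("module / background split and between-module independence", {
  cfg <- syntheticConfig(nGenes = 120L, nSamples = 100L, nCase = 50L,
                         moduleSizes = rep(20L, 3), withinModuleCor = 0.9,
                         discriminativeModules = integer(0), effectSize = 0,
                         annotationSize = 1L, annotationOverlap = 0L,
                         seed = 13)
  se <- simulateCoexpression(cfg)
  mod <- S4Vectors::metadata(se)$groundTruth$module_of_gene
  expect_identical(sum(mod > 0), 60L)
  expect_identical(sum(mod == 0), 60L)
  X <- log2(SummarizedExperiment::assay(se))
  between <- c()
  for (a in 1:2) for (b in (a + 1):3) {
    C <- cor(t(X[names(mod)[mod == a], ]), t(X[names(mod)[mod == b], ]))
    between <- c(between, as.vector(C))
  }
  expect_lt(abs(mean(between)), 0.05)
})

test_that("null world yields uniform per-gene t-test p-values", {
  cfg <- syntheticConfig(nGenes = 1000L, nSamples = 100L, nCase = 50L,
                         moduleSizes = 10L, withinModuleCor = 0.5,
                         discriminativeModules = integer(0), effectSize = 0,
                         annotationSize = 1L, annotationOverlap = 0L,
                         seed = 19)
  se <- simulateCoexpression(cfg)
  X <- log2(SummarizedExperiment::assay(se))
  classes <- S4Vectors::metadata(se)$groundTruth$class_of_sample
  pvals <- apply(X[S4Vectors::metadata(se)$groundTruth$module_of_gene == 0, ],
                 1, function(v)
                   t.test(v[classes == "case"], v[classes == "control"])$p.value)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("matched seeds isolate the effect-size parameter", {
  base <- list(nGenes = 40L, nSamples = 60L, nCase = 30L,
               moduleSizes = c(20L, 10L), withinModuleCor = 0.5,
               discriminativeModules = 1L, informativeFraction = 0.5,
               annotationSize = 2L, annotationOverlap = 2L, seed = 3)
  se0 <- simulateCoexpression(do.call(syntheticConfig, c(base, effectSize = 0)))
  se2 <- simulateCoexpression(do.call(syntheticConfig, c(base, effectSize = 2)))
  X0 <- log2(SummarizedExperiment::assay(se0))
  X2 <- log2(SummarizedExperiment::assay(se2))
  truth <- S4Vectors::metadata(se0)$groundTruth
  inf <- truth$informative_genes
  cases <- names(truth$class_of_sample)[truth$class_of_sample == "case"]
  ctls <- setdiff(colnames(se0), cases)
  # untouched entries identical; informative case entries shifted by 2
  expect_equal(X0[setdiff(rownames(X0), inf), ], X2[setdiff(rownames(X0), inf), ])
  expect_equal(X0[inf, ctls], X2[inf, ctls])
  expect_equal(X2[inf, cases] - X0[inf, cases],
               matrix(2, length(inf), length(cases),
                      dimnames = list(inf, cases)))
})

test_that("writeDataset round-trips exactly and its files are coherent", {
  cfg <- syntheticConfig(nGenes = 30L, nSamples = 12L, nCase = 6L,
                         moduleSizes = c(10L, 10L), nBatches = 2L,
                         batchShiftSd = 0.5, annotationSize = 4L,
                         annotationOverlap = 3L, seed = 4)
  se <- simulateCoexpression(cfg)
  dir <- withr::local_tempdir()
  paths <- writeDataset(se, dir)
  expect_true(all(file.exists(paths)))

  back <- readDataset(paths[["expression"]], paths[["metadata"]])
  expect_identical(SummarizedExperiment::assay(back),
                   SummarizedExperiment::assay(se))
  md <- read.delim(paths[["metadata"]])
  expect_identical(nrow(md), 12L)
  expect_identical(sort(unique(md$class)), c("case", "control"))

  truth <- jsonlite::read_json(paths[["ground_truth"]], simplifyVector = TRUE)
  expect_true(all(truth$informative_genes %in% rownames(se)))
  expect_true(all(truth$annotation_set %in% rownames(se)))
  gmt <- readGMT(paths[["annotation"]])
  expect_identical(sort(gmt[[1]]),
                   sort(S4Vectors::metadata(se)$groundTruth$annotation_set))
})

test_that("informative genes live inside discriminative modules", {
  cfg <- syntheticConfig(seed = 8, discriminativeModules = c(2L, 4L),
                         effectSize = 1)
  truth <- S4Vectors::metadata(simulateCoexpression(cfg))$groundTruth
  inModules <- names(truth$module_of_gene)[
    truth$module_of_gene %in% truth$discriminative_modules]
  expect_true(all(truth$informative_genes %in% inModules))
  expect_identical(sort(unique(truth$class_of_sample)), c("case", "control"))
})

test_that("hierarchical generator plants the two-level correlation structure", {
  se <- simulateHierarchicalCoexpression(superSizes = c(40L, 40L),
                                         subBlocksPerSuper = 2L,
                                         rhoSuper = 0.4, rhoSub = 0.8,
                                         nSamples = 300L, seed = 2)
  X <- log2(SummarizedExperiment::assay(se))
  sub <- SummarizedExperiment::rowData(se)$sub
  sup <- SummarizedExperiment::rowData(se)$super
  C <- cor(t(X))
  sameSub <- outer(sub, sub, "==") & upper.tri(C)
  sameSuperOnly <- outer(sup, sup, "==") & !outer(sub, sub, "==") & upper.tri(C)
  crossSuper <- !outer(sup, sup, "==") & upper.tri(C)
  expect_equal(mean(C[sameSub]), 0.8, tolerance = 0.05)
  expect_equal(mean(C[sameSuperOnly]), 0.4, tolerance = 0.05)
  expect_lt(abs(mean(C[crossSuper])), 0.05)
})
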