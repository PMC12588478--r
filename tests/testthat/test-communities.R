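test_that("NMI conventions and brute-force equivalence", {
  nodes <- as.character(1:6)
  p <- setNames(c(1, 1, 1, 2, 2, 2), nodes)
  q <- setNames(c(1, 1, 2, 2, 2, 2), nodes)
  expect_equal(partitionNMI(p, p), 1.0)
  expect_equal(partitionNMI(p, setNames(rep(1, 6), nodes)), 0.0)
  expect_equal(partitionNMI(setNames(rep(1, 6), nodes),
                            setNames(rep(2, 6), nodes)), 1.0)
  expect_equal(partitionNMI(p, q), nmiOracle(p, q), tolerance = 1e-14)
  # symmetry and label-permutation invariance
  expect_identical(partitionNMI(p, q), partitionNMI(q, p))
  expect_identical(partitionNMI(p, q),
                   partitionNMI(setNames(c(7, 7, 7, 3, 3, 3), nodes), q))
  expect_error(partitionNMI(p, setNames(1:5, as.character(1:5))), "node set")
})

test_that("NMI agrees with igraph's implementation on random partitions", {
  set.seed(71)
  nodes <- sprintf("n%02d", 1:15)
  for (i in 1:20) {
    p <- randomPartition(nodes, 4)
    q <- randomPartition(nodes, 3)
    if (length(unique(p)) < 2 || length(unique(q)) < 2) next
    expect_equal(partitionNMI(p, q),
                 igraph::compare(p[nodes], q[nodes], method = "nmi"),
                 tolerance = 1e-12)
  }
})

test_that("average pairwise NMI equals the explicit double loop", {
  set.seed(12)
  nodes <- sprintf("n%02d", 1:12)
  parts <- lapply(1:5, function(i) randomPartition(nodes, 3))
  loop <- 0
  for (a in 1:4) for (b in (a + 1):5)
    loop <- loop + partitionNMI(parts[[a]], parts[[b]])
  expect_equal(averagePairwiseNMI(parts), loop / 10, tolerance = 1e-12)

  same <- replicate(6, parts[[1]], simplify = FALSE)
  expect_identical(averagePairwiseNMI(same), 1)
  tri <- parts[1:3]
  abc <- c(partitionNMI(tri[[1]], tri[[2]]), partitionNMI(tri[[1]], tri[[3]]),
           partitionNMI(tri[[2]], tri[[3]]))
  expect_equal(averagePairwiseNMI(tri), mean(abc), tolerance = 1e-14)
  expect_error(averagePairwiseNMI(parts[1]), "2 partitions")
})

test_that("canonical form renumbers labels by name-sorted first appearance", {
  m <- c(b = 10L, a = 20L, c = 10L)
  canon <- canonicalPartition(m)
  expect_identical(canon, c(a = 0L, b = 1L, c = 1L))
  expect_error(canonicalPartition(1:3), "named")
})

test_that("the Leiden ensemble finds planted cliques deterministically", {
  net <- cliqueNet(c(10, 10), wBridge = 0.2)
  parts <- runLeidenEnsemble(net, gamma = 1, beta = 0.01, L = 20, baseSeed = 5)
  expect_length(parts, 20)
  truth <- canonicalPartition(setNames(rep(1:2, each = 10), networkNodes(net)))
  for (p in parts) expect_identical(p, truth)
  parts2 <- runLeidenEnsemble(net, gamma = 1, beta = 0.01, L = 20, baseSeed = 5)
  expect_identical(parts, parts2)
  empty <- methods::new("CoexpressionNetwork", nodes = character(0),
                        edges = networkEdges(net)[0, ], alpha = 0.01)
  expect_error(runLeidenEnsemble(empty, 1, 0.01), "empty")
})

test_that("majority voting and its deterministic tie-breaks", {
  nodes <- as.character(1:6)
  P <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L), nodes)
  Q <- setNames(c(0L, 0L, 1L, 1L, 1L, 1L), nodes)
  R <- setNames(c(0L, 1L, 0L, 1L, 0L, 1L), nodes)
  expect_identical(majorityPartition(list(P, P, Q)),
                   list(partition = P, frequency = 2L))
  expect_identical(majorityPartition(list(P)),
                   list(partition = P, frequency = 1L))
  # tie between P and Q: P is closer (higher average NMI) to the ensemble
  tie <- majorityPartition(list(P, P, Q, Q, R))
  avgP <- mean(sapply(list(P, P, Q, Q, R), partitionNMI, p = P))
  avgQ <- mean(sapply(list(P, P, Q, Q, R), partitionNMI, p = Q))
  expect_identical(tie$partition, if (avgP >= avgQ) P else Q)
  expect_identical(tie$frequency, 2L)
})

test_that("the three retention criteria are evaluated as defined", {
  net <- cliqueNet(c(10, 10), wBridge = 0.2)
  rep <- evaluateConfig(net, gamma = 1, beta = 0.01, L = 20, baseSeed = 5)
  expect_true(rep@stable && rep@substantial && rep@nonfragmented)
  expect_true(isRetained(rep))
  expect_equal(meanNMI(rep), 1.0)
  expect_identical(rep@majorityFrequency, 20L)

  # tiny gamma merges everything -> not substantial
  rep1 <- evaluateConfig(net, gamma = 1e-4, beta = 0.01, L = 10, baseSeed = 5)
  expect_false(rep1@substantial)
  expect_false(isRetained(rep1))

  # a 2-node appendage fragments the partition at minFraction = 0.2
  net3 <- cliqueNet(c(10, 10, 2), wBridge = 0.2)
  rep2 <- evaluateConfig(net3, gamma = 1, beta = 0.01, L = 10, baseSeed = 5,
                         minFraction = 0.2)
  expect_false(rep2@nonfragmented)
})

test_that("grid selection prefers retained configs and reports the grid", {
  net <- cliqueNet(c(10, 10), wBridge = 0.2)
  sel <- selectStableConfig(net, gammaGrid = c(1e-4, 1), betaGrid = 0.01,
                            L = 10, baseSeed = 5)
  expect_true(isRetained(sel))
  expect_equal(sel@gamma, 1)
  grid <- attr(sel, "grid")
  expect_identical(nrow(grid), 2L)
  expect_identical(sum(grid$retained), 1L)
  expect_error(selectStableConfig(net, gammaGrid = numeric(0)), "grid")
})

test_that("hierarchical detection handles in-band graphs and discards tiny communities", {
  net <- cliqueNet(c(10, 8, 3), wBridge = 0.2)
  expect_warning(
    cs <- detectCommunities(net, minSize = 4, maxSize = 100,
                            gammaGrid = c(0.8, 1), betaGrid = 0.01, L = 10,
                            baseSeed = 5, minFraction = 0.05),
    regexp = NA)
  rec <- communityRecords(cs)
  expect_true(all(rec$final))
  expect_setequal(rec$size, c(10L, 8L))
  disc <- discardedCommunities(cs)
  expect_identical(nrow(disc), 1L)
  expect_identical(disc$size, 3L)
  # depth-1 recursion: every hierarchy path is a single level
  expect_false(any(grepl("/", rec$hierarchy_path)))
})

test_that("hierarchical detection is fully deterministic", {
  net <- cliqueNet(c(12, 10, 8), wBridge = 0.2)
  run <- function() detectCommunities(net, gammaGrid = c(0.8, 1.2),
                                      betaGrid = c(0.01, 0.05), L = 10,
                                      baseSeed = 77)
  cs1 <- run(); cs2 <- run()
  expect_identical(communityRecords(cs1), communityRecords(cs2))
  expect_identical(finalCommunities(cs1), finalCommunities(cs2))
})

test_that("final records are disjoint and nested within level-1 communities", {
  se <- simulateHierarchicalCoexpression(superSizes = c(60L, 60L),
                                         subBlocksPerSuper = 3L,
                                         rhoSuper = 0.4, rhoSub = 0.8,
                                         nSamples = 80L, seed = 14)
  net <- buildNetwork(log2Transform(se))
  cs <- detectCommunities(net, maxSize = 30, gammaGrid = c(0.5, 1),
                          betaGrid = 0.01, L = 10, baseSeed = 2)
  fin <- finalCommunities(cs)
  genes <- unlist(fin)
  expect_identical(anyDuplicated(genes), 0L)
  rec <- communityRecords(cs)
  level1 <- rec[!grepl("/", rec$hierarchy_path), "community_id"]
  for (id in names(fin)) {
    top <- sub("/.*$", "", rec$hierarchy_path[rec$community_id == id])
    expect_true(paste0("C", top) %in% level1 || id %in% level1)
    expect_true(all(fin[[id]] %in% communityGenes(cs, paste0("C", top))))
  }
})
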