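# shared fixtures, built in code at test time

# SummarizedExperiment from a plain matrix + labels
makeSE <- function(X, classes = NULL, batches = NULL) {
  if (is.null(classes))
    classes <- rep(c("case", "control"), length.out = ncol(X))
  if (is.null(batches)) batches <- rep("b1", ncol(X))
  if (is.null(rownames(X))) rownames(X) <- sprintf("g%03d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("s%03d", seq_len(ncol(X)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = X),
    colData = S4Vectors::DataFrame(class = classes, batch = batches,
                                   row.names = colnames(X)))
}

# hand-built weighted network: cliques of the given sizes, optionally tied
# together by single weak bridge edges
cliqueNet <- function(sizes, wIn = 0.9, wBridge = 0.25) {
  nodes <- sprintf("n%03d", seq_len(sum(sizes)))
  block <- rep(seq_along(sizes), sizes)
  edges <- list()
  for (b in seq_along(sizes)) {
    ids <- nodes[block == b]
    if (length(ids) > 1) {
      pairs <- utils::combn(ids, 2)
      edges[[length(edges) + 1]] <- data.frame(
        gene_a = pairs[1, ], gene_b = pairs[2, ], r = wIn, weight = wIn,
        p = 1e-8, stringsAsFactors = FALSE)
    }
  }
  if (length(sizes) > 1) {
    for (b in seq_len(length(sizes) - 1)) {
      edges[[length(edges) + 1]] <- data.frame(
        gene_a = nodes[block == b][1], gene_b = nodes[block == b + 1][1],
        r = wBridge, weight = wBridge, p = 1e-3, stringsAsFactors = FALSE)
    }
  }
  methods::new("CoexpressionNetwork", nodes = nodes,
               edges = do.call(rbind, edges), alpha = 0.01)
}

# independent NMI oracle: direct contingency-table entropy computation,
# written without the package's internals
nmiOracle <- function(p, q) {
  p <- p[order(names(p))]; q <- q[order(names(q))]
  n <- length(p)
  tab <- table(as.vector(p), as.vector(q))
  pij <- tab / n
  pa <- rowSums(pij); pb <- colSums(pij)
  H <- function(v) { v <- v[v > 0]; -sum(unname(v) * log(unname(v))) }
  Ha <- H(pa); Hb <- H(pb)
  if (Ha == 0 && Hb == 0) return(1)
  if (Ha == 0 || Hb == 0) return(0)
  I <- 0
  for (i in seq_len(nrow(pij))) for (j in seq_len(ncol(pij)))
    if (pij[i, j] > 0) I <- I + pij[i, j] * log(pij[i, j] / (pa[i] * pb[j]))
  unname(2 * I / (Ha + Hb))
}

randomPartition <- function(nodes, k) {
  stats::setNames(sample.int(k, length(nodes), replace = TRUE), nodes)
}

# best-match Jaccard of each truth set against a list of detected sets
bestMatchJaccard <- function(truthSets, detected) {
  vapply(truthSets, function(genes)
    max(vapply(detected, function(d)
      length(intersect(d, genes)) / length(union(d, genes)), numeric(1))),
    numeric(1))
}

# planted two-community (30 + 30) expression world used by the ML tests:
# module 1 carries 10 informative genes at the given effect size, module 2
# is pure noise with matched within-module correlation
mlWorld <- function(effectSize = 2, seed = 21, nSamples = 200L) {
  cfg <- syntheticConfig(nGenes = 60L, nSamples = nSamples,
                         nCase = nSamples %/% 2L,
                         moduleSizes = c(30L, 30L), withinModuleCor = 0.3,
                         discriminativeModules = 1L, effectSize = effectSize,
                         informativeFraction = 1 / 3, annotationSize = 1L,
                         annotationOverlap = 1L, seed = seed)
  se <- simulateCoexpression(cfg)
  # log2 only: quantile normalization would bleed a compensatory class
  # signal from the shifted genes into the null module
  se <- preprocessExpression(se, steps = "log2")
  truth <- S4Vectors::metadata(se)$groundTruth
  list(se = se, truth = truth,
       disc = names(truth$module_of_gene)[truth$module_of_gene == 1],
       null = names(truth$module_of_gene)[truth$module_of_gene == 2])
}
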