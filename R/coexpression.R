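#' Build the significance-filtered co-expression network
#'
#' For every gene pair the Pearson correlation r across samples is tested
#' against H0: rho = 0 with the exact t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom (two
#' sided). A pair is linked iff p < alpha — the two-sided test at level 0.01
#' is equivalent to the 99% confidence interval excluding zero. The
#' clustering weight is |r|; the signed correlation is kept as an edge
#' attribute. Constant genes cannot be tested and are dropped with a warning.
#'
#' @param se `SummarizedExperiment` or genes x samples matrix (>= 4 samples).
#' @param alpha edge significance level (default 0.01).
#' @return a [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(se, alpha = 0.01) {
  X <- .exprsOf(se)
  n <- ncol(X)
  if (n < 4) stop("network construction needs at least 4 samples")
  v <- apply(X, 1, stats::var)
  if (any(v <= 0)) {
    warning(sprintf("dropping %d constant gene(s)", sum(v <= 0)))
    X <- X[v > 0, , drop = FALSE]
  }
  if (nrow(X) == 0) stop("all genes are constant; empty network")
  genes <- rownames(X)
  C <- cor(t(X))
  ut <- upper.tri(C)
  r <- C[ut]
  # clamp rounding spill so t is finite where |r| < 1 and +-Inf at |r| = 1
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  keep <- which(p < alpha)
  ij <- which(ut, arr.ind = TRUE)[keep, , drop = FALSE]
  edges <- data.frame(gene_a = genes[ij[, 1]], gene_b = genes[ij[, 2]],
                      r = r[keep], weight = abs(r[keep]), p = p[keep],
                      stringsAsFactors = FALSE)
  new("CoexpressionNetwork", nodes = genes, edges = edges, alpha = alpha)
}

#' Induced subgraph on a gene subset
#'
#' Keeps exactly the listed genes and every original edge with both endpoints
#' in the set. Edge attributes are carried over unchanged — correlations are
#' NOT recomputed on the subset.
#'
#' @param net a `CoexpressionNetwork`.
#' @param genes character vector, subset of the network's nodes.
#' @return a `CoexpressionNetwork` on `genes`.
#' @export
inducedSubgraph <- function(net, genes) {
  unknown <- setdiff(genes, net@nodes)
  if (length(unknown) > 0)
    stop("unknown gene(s): ", paste(head(unknown, 5), collapse = ", "))
  e <- net@edges
  e <- e[e$gene_a %in% genes & e$gene_b %in% genes, , drop = FALSE]
  rownames(e) <- NULL
  new("CoexpressionNetwork", nodes = genes, edges = e, alpha = net@alpha)
}

#' Convert a CoexpressionNetwork to an igraph object
#'
#' @param net a `CoexpressionNetwork`.
#' @return an undirected `igraph` graph with the `weight` edge attribute set
#'   to |r| and `r`/`p` carried along; isolated genes are kept as vertices.
#' @export
asIgraph <- function(net) {
  igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                vertices = data.frame(name = net@nodes))
}

#' Write / read the edge-list TSV dialect
#'
#' Columns `gene_a`, `gene_b`, `r`, `weight`, `p`; values round-trip to at
#' least 12 significant digits. An empty network writes a header-only file.
#'
#' @param net a `CoexpressionNetwork`.
#' @param path file path.
#' @return `writeEdgeList` the path, invisibly; `readEdgeList` a
#'   `CoexpressionNetwork`.
#' @export
writeEdgeList <- function(net, path) {
  e <- net@edges
  out <- data.frame(gene_a = e$gene_a, gene_b = e$gene_b,
                    r = sprintf("%.15g", e$r),
                    weight = sprintf("%.15g", e$weight),
                    p = sprintf("%.15g", e$p), stringsAsFactors = FALSE)
  if (nrow(e) == 0) out <- out[0, ]
  header <- sprintf("# nodes=%s alpha=%.15g", paste(net@nodes, collapse = ","),
                    net@alpha)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "# nodes="))
    stop("malformed edge list: missing node header (line 1)")
  hdr <- sub("^# nodes=", "", lines[1])
  alpha <- as.numeric(sub(".* alpha=", "", hdr))
  nodes <- strsplit(sub(" alpha=.*$", "", hdr), ",", fixed = TRUE)[[1]]
  cols <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (!identical(cols, c("gene_a", "gene_b", "r", "weight", "p")))
    stop("malformed edge list: bad column header (line 2)")
  body <- lines[-(1:2)]
  if (length(body) == 0) {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        r = numeric(0), weight = numeric(0), p = numeric(0))
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 5)
    if (length(bad) > 0)
      stop(sprintf("malformed edge list row at line %d", bad[1] + 2))
    m <- do.call(rbind, parts)
    edges <- data.frame(gene_a = m[, 1], gene_b = m[, 2],
                        r = as.numeric(m[, 3]), weight = as.numeric(m[, 4]),
                        p = as.numeric(m[, 5]), stringsAsFactors = FALSE)
    key <- paste(pmin(edges$gene_a, edges$gene_b),
                 pmax(edges$gene_a, edges$gene_b))
    dup <- which(duplicated(key))
    if (length(dup) > 0)
      stop(sprintf("duplicate gene pair at line %d", dup[1] + 2))
  }
  new("CoexpressionNetwork", nodes = nodes, edges = edges, alpha = alpha)
}

#' Small JSON summary of a network
#' @param net a `CoexpressionNetwork`
#' @param path output path
#' @return the path, invisibly
#' @export
writeNetworkSummary <- function(net, path) {
  n <- length(net@nodes)
  jsonlite::write_json(list(nodes = n, edges = nrow(net@edges),
                            density = if (n > 1) nrow(net@edges) / (n * (n - 1) / 2) else 0,
                            alpha = net@alpha),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
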