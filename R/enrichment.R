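#' Read / write gene-set collections in GMT format
#'
#' Standard dialect: one set per line — name, description, then tab-separated
#' gene ids.
#'
#' @param path file path.
#' @return `readGMT`: named list of character vectors with the descriptions
#'   attached as attribute `"description"`.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0)
    stop(sprintf("malformed GMT record at line %d (need name, description, >= 1 gene)",
                 bad[1]))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicated gene-set names in GMT")
  attr(sets, "description") <- setNames(
    vapply(parts, `[[`, character(1), 2), names(sets))
  sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @param description single string or per-set character vector.
#' @export
writeGMT <- function(sets, path, description = "") {
  desc <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of one community in one gene set
#'
#' Upper-tail test: with a universe of `N_u` genes of which `K` belong to the
#' annotation set, drawing the `n` community genes without replacement, the
#' p-value is `P(X >= k)` for the observed overlap `k`,
#' X ~ Hypergeometric(N_u, K, n). The annotation set is intersected with the
#' universe before testing.
#'
#' @param communityGenes genes of the community (must all be in `universe`).
#' @param setGenes annotation gene set.
#' @param universe the sampling frame — by convention all genes of the
#'   co-expression network, since communities can only draw from those.
#' @param setName,communityId labels for the result row.
#' @return one-row data.frame: community_id, set_name, universe_size,
#'   set_size, community_size, overlap, overlap_genes, p.
#' @export
hypergeomOverrep <- function(communityGenes, setGenes, universe,
                             setName = "set", communityId = "community") {
  outside <- setdiff(communityGenes, universe)
  if (length(outside) > 0)
    stop("community gene(s) outside the universe: ",
         paste(head(outside, 5), collapse = ", "))
  K <- length(intersect(setGenes, universe))
  n <- length(unique(communityGenes))
  ov <- intersect(communityGenes, intersect(setGenes, universe))
  k <- length(ov)
  Nu <- length(unique(universe))
  p <- phyper(k - 1, K, Nu - K, n, lower.tail = FALSE)
  data.frame(community_id = communityId, set_name = setName,
             universe_size = Nu, set_size = K, community_size = n,
             overlap = k, overlap_genes = paste(sort(ov), collapse = ","),
             p = p, stringsAsFactors = FALSE)
}

#' Over-representation of every community against every gene set
#'
#' One hypergeometric test per (community, set) pair. Two significance
#' conventions are reported: the raw p-value at `alphaSingle` (the
#' single-annotation, risk-gene-list style test at the 1% level) and the
#' Bonferroni-corrected p at `alphaBonferroni` (the multi-set collection
#' convention), with `p_bonferroni = min(1, p * number of sets)`.
#'
#' @param communities named list of gene vectors (e.g.
#'   [finalCommunities()]).
#' @param collection named list of annotation gene sets (e.g. [readGMT()]).
#' @param universe the gene universe.
#' @param alphaSingle raw-p significance level (default 0.01).
#' @param alphaBonferroni corrected-p significance level (default 0.05).
#' @return data.frame with one row per (community, set) pair, p,
#'   p_bonferroni and both significance flags.
#' @export
enrichCommunities <- function(communities, collection, universe,
                              alphaSingle = 0.01, alphaBonferroni = 0.05) {
  if (length(universe) == 0) stop("empty universe")
  if (length(communities) == 0 || length(collection) == 0)
    stop("communities and collection must be nonempty")
  m <- length(collection)
  rows <- list()
  for (ci in names(communities)) {
    for (si in names(collection)) {
      rows[[length(rows) + 1]] <-
        hypergeomOverrep(communities[[ci]], collection[[si]], universe,
                         setName = si, communityId = ci)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * m)
  out$significant_raw <- out$p < alphaSingle
  out$significant_bonferroni <- out$p_bonferroni < alphaBonferroni
  out
}
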