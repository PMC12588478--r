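#' CoexpressionNetwork: a significance-filtered weighted gene graph
#'
#' Nodes are genes; an edge joins two genes whose Pearson correlation across
#' samples is significant at the configured level. Each edge carries the
#' signed correlation `r`, the nonnegative clustering weight (|r|) and the
#' two-sided p-value of the correlation t-test.
#'
#' @slot nodes character vector of gene identifiers.
#' @slot edges data.frame with columns `gene_a`, `gene_b`, `r`, `weight`, `p`.
#' @slot alpha significance level used to retain edges.
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
  representation(nodes = "character", edges = "data.frame", alpha = "numeric"))

setValidity("CoexpressionNetwork", function(object) {
  e <- object@edges
  need <- c("gene_a", "gene_b", "r", "weight", "p")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(object@nodes)) return("duplicated node ids")
  if (nrow(e) > 0) {
    if (!all(e$gene_a %in% object@nodes) || !all(e$gene_b %in% object@nodes))
      return("edge endpoint not among nodes")
    if (any(e$gene_a == e$gene_b)) return("self-loop edge")
    key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
    if (anyDuplicated(key)) return("duplicated gene pair")
    if (any(abs(e$r) > 1 + 1e-12)) return("|r| > 1")
    if (any(e$weight <= 0)) return("nonpositive edge weight")
    if (any(e$p >= object@alpha)) return("edge with p >= alpha retained")
  }
  TRUE
})

#' @describeIn CoexpressionNetwork gene identifiers of the network
#' @param x,object a `CoexpressionNetwork`
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn CoexpressionNetwork edge table (gene_a, gene_b, r, weight, p)
#' @export
networkEdges <- function(x) x@edges

#' @describeIn CoexpressionNetwork significance level used when building
#' @export
networkAlpha <- function(x) x@alpha

setMethod("show", "CoexpressionNetwork", function(object) {
  n <- length(object@nodes)
  m <- nrow(object@edges)
  dens <- if (n > 1) m / (n * (n - 1) / 2) else 0
  cat(sprintf("CoexpressionNetwork: %d genes, %d edges (density %.4f, alpha %g)\n",
              n, m, dens, object@alpha))
})

#' StabilityReport: outcome of one Leiden ensemble configuration
#'
#' Summarises L stochastic Leiden runs at one (gamma, beta) configuration:
#' the ensemble's mean pairwise normalized mutual information, the majority
#' partition with its frequency, and the three retention criteria
#' (stability, substantiality, non-fragmentation).
#'
#' @slot gamma,beta Leiden resolution and randomness parameters.
#' @slot L number of ensemble runs.
#' @slot meanNMI mean pairwise NMI over the L(L-1)/2 run pairs.
#' @slot majorityPartition named integer vector (canonical form) of the most
#'   frequent partition.
#' @slot majorityFrequency how many runs produced the majority partition.
#' @slot stable,substantial,nonfragmented,retained logical criteria flags;
#'   `retained` is their conjunction.
#' @exportClass StabilityReport
setClass("StabilityReport",
  representation(gamma = "numeric", beta = "numeric", L = "integer",
                 meanNMI = "numeric", majorityPartition = "integer",
                 majorityFrequency = "integer", stable = "logical",
                 substantial = "logical", nonfragmented = "logical",
                 retained = "logical"))

setValidity("StabilityReport", function(object) {
  if (object@majorityFrequency > object@L) return("majorityFrequency > L")
  if (object@retained && !(object@stable && object@substantial && object@nonfragmented))
    return("retained implies all three criteria")
  if (object@meanNMI < -1e-12 || object@meanNMI > 1 + 1e-12)
    return("meanNMI outside [0, 1]")
  TRUE
})

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf(
    "StabilityReport: gamma=%g beta=%g L=%d <NMI>=%.4f K=%d (freq %d/%d)\n  stable=%s substantial=%s nonfragmented=%s -> retained=%s\n",
    object@gamma, object@beta, object@L, object@meanNMI,
    length(unique(object@majorityPartition)), object@majorityFrequency,
    object@L, object@stable, object@substantial, object@nonfragmented,
    object@retained))
})

#' @describeIn StabilityReport the majority partition (named integer vector)
#' @param x a `StabilityReport`
#' @export
majorityMembership <- function(x) x@majorityPartition

#' @describeIn StabilityReport mean pairwise NMI of the ensemble
#' @export
meanNMI <- function(x) x@meanNMI

#' @describeIn StabilityReport whether the configuration passed all criteria
#' @export
isRetained <- function(x) x@retained

#' CommunitySet: result of hierarchical community detection
#'
#' @slot records data.frame with one row per discovered community:
#'   `community_id`, `size`, `hierarchy_path` (slash-separated lineage),
#'   `final` (inside the size band).
#' @slot membership named list: community_id -> character vector of genes.
#' @slot discarded data.frame of communities below the minimum size.
#' @slot reports list of `StabilityReport`, one per recursion node, named by
#'   hierarchy path.
#' @exportClass CommunitySet
setClass("CommunitySet",
  representation(records = "data.frame", membership = "list",
                 discarded = "data.frame", reports = "list"))

setValidity("CommunitySet", function(object) {
  if (!setequal(object@records$community_id, names(object@membership)))
    return("records and membership disagree")
  fin <- object@records$community_id[object@records$final]
  genes <- unlist(object@membership[fin], use.names = FALSE)
  if (anyDuplicated(genes)) return("final communities are not disjoint")
  TRUE
})

setMethod("show", "CommunitySet", function(object) {
  fin <- sum(object@records$final)
  cat(sprintf("CommunitySet: %d communities (%d final), %d discarded (< min size)\n",
              nrow(object@records), fin, nrow(object@discarded)))
})

#' @describeIn CommunitySet named list of gene vectors for final communities
#' @param x a `CommunitySet`
#' @export
finalCommunities <- function(x) {
  x@membership[x@records$community_id[x@records$final]]
}

#' @describeIn CommunitySet full community table
#' @export
communityRecords <- function(x) x@records

#' @describeIn CommunitySet genes of one community
#' @param id community identifier
#' @export
communityGenes <- function(x, id) {
  if (!id %in% names(x@membership)) stop("unknown community id: ", id)
  x@membership[[id]]
}

#' @describeIn CommunitySet table of discarded (too small) communities
#' @export
discardedCommunities <- function(x) x@discarded

#' @describeIn CommunitySet stability reports per recursion node
#' @export
stabilityReports <- function(x) x@reports

#' CommunityPerformance: cross-validated classification of one community
#'
#' @slot communityId community identifier.
#' @slot genes genes used as the candidate feature set.
#' @slot metrics named numeric vector: accuracy/auc/f1 means and SDs across
#'   repetition-level means.
#' @slot borutaAvgSelected average number of Boruta-confirmed genes per
#'   fold x repetition (the top-gene count N).
#' @slot geneFrequency named selection counts over all folds x repetitions.
#' @slot geneImportance named mean Boruta importance.
#' @slot topGenes the round(N) most frequently selected genes.
#' @slot nFolds,nRepetitions CV geometry used.
#' @exportClass CommunityPerformance
setClass("CommunityPerformance",
  representation(communityId = "character", genes = "character",
                 metrics = "numeric", borutaAvgSelected = "numeric",
                 geneFrequency = "numeric", geneImportance = "numeric",
                 topGenes = "character", nFolds = "integer",
                 nRepetitions = "integer"))

setValidity("CommunityPerformance", function(object) {
  need <- c("accuracy_mean", "accuracy_sd", "auc_mean", "auc_sd",
            "f1_mean", "f1_sd")
  if (!all(need %in% names(object@metrics))) return("missing metric entries")
  m <- object@metrics[c("accuracy_mean", "auc_mean", "f1_mean")]
  if (any(m < -1e-12 | m > 1 + 1e-12)) return("metric outside [0, 1]")
  if (object@borutaAvgSelected > length(object@genes) + 1e-9)
    return("N exceeds community size")
  if (length(object@topGenes) != round(object@borutaAvgSelected))
    return("top_genes must have round(N) entries")
  TRUE
})

setMethod("show", "CommunityPerformance", function(object) {
  m <- object@metrics
  cat(sprintf(
    "CommunityPerformance %s (%d genes, %d-fold CV x %d reps)\n  accuracy %.3f +/- %.3f | AUC %.3f +/- %.3f | F1 %.3f +/- %.3f\n  Boruta N = %.2f -> top genes: %s\n",
    object@communityId, length(object@genes), object@nFolds,
    object@nRepetitions, m["accuracy_mean"], m["accuracy_sd"], m["auc_mean"],
    m["auc_sd"], m["f1_mean"], m["f1_sd"], object@borutaAvgSelected,
    paste(object@topGenes, collapse = ", ")))
})

#' @describeIn CommunityPerformance named metric vector
#' @param x a `CommunityPerformance`
#' @export
performanceMetrics <- function(x) x@metrics

#' @describeIn CommunityPerformance the top-N gene list
#' @export
topGenes <- function(x) x@topGenes

#' @describeIn CommunityPerformance per-gene Boruta selection counts
#' @export
geneSelectionFrequency <- function(x) x@geneFrequency

#' @describeIn CommunityPerformance average confirmed-feature count N
#' @export
borutaAvgSelected <- function(x) x@borutaAvgSelected

#' AttributionMatrix: per-sample, per-gene Shapley values
#'
#' Satisfies local accuracy: `baseValue + rowSums(values)` equals the model
#' output for every explained sample (within numerical tolerance).
#'
#' @slot values samples x features matrix of Shapley values.
#' @slot baseValue expected model output over the background sample.
#' @slot modelOutput model output per explained sample.
#' @slot featureValues the explained samples' feature values (same shape as
#'   `values`), kept for beeswarm-style export.
#' @exportClass AttributionMatrix
setClass("AttributionMatrix",
  representation(values = "matrix", baseValue = "numeric",
                 modelOutput = "numeric", featureValues = "matrix"))

setValidity("AttributionMatrix", function(object) {
  if (!identical(dim(object@values), dim(object@featureValues)))
    return("values and featureValues shapes differ")
  gap <- abs(object@baseValue + rowSums(object@values) - object@modelOutput)
  if (any(gap > 1e-6))
    return(sprintf("local accuracy violated (max gap %.3g)", max(gap)))
  TRUE
})

setMethod("show", "AttributionMatrix", function(object) {
  cat(sprintf("AttributionMatrix: %d samples x %d features, base value %.4f\n",
              nrow(object@values), ncol(object@values), object@baseValue))
})

#' @describeIn AttributionMatrix the Shapley value matrix
#' @param x an `AttributionMatrix`
#' @export
shapValues <- function(x) x@values

#' @describeIn AttributionMatrix expected model output over the background
#' @export
baseValue <- function(x) x@baseValue
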