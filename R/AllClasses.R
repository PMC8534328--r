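#' Seed-cluster entropy state
#'
#' Snapshot of the binary graph-entropy decomposition induced by one seed
#' cluster: the graph is split into the cluster and everything else, and
#' every node contributes the entropy of its edge distribution across that
#' boundary. Produced by [clusterEntropy()] and queried by
#' [deltaEntropyMove()], [prunePhase()] and [growthPhase()].
#'
#' @slot graph the underlying `igraph` object.
#' @slot mode entropy mode, one of `"unweighted"`, `"ge-mw"`, `"ge-wr"`.
#' @slot cluster character vector of cluster member node names.
#' @slot nodeEntropy named numeric, per-node entropy in bits.
#' @slot totalEntropy total graph entropy (sum of `nodeEntropy`).
#' @slot insideCount named integer, per-node count of edges into the cluster.
#' @slot insideWeight named numeric, per-node weight sum of edges into the
#'   cluster.
#'
#' @export
setClass("SeedClusterState",
  representation(
    graph = "ANY",
    mode = "character",
    cluster = "character",
    nodeEntropy = "numeric",
    totalEntropy = "numeric",
    insideCount = "integer",
    insideWeight = "numeric"
  )
)

setValidity("SeedClusterState", function(object) {
  msg <- character(0)
  if (length(object@cluster) < 1)
    msg <- c(msg, "cluster must be non-empty")
  if (!inherits(object@graph, "igraph"))
    msg <- c(msg, "graph must be an igraph object")
  else {
    nm <- igraph::V(object@graph)$name
    if (!all(object@cluster %in% nm))
      msg <- c(msg, "cluster contains nodes absent from the graph")
    if (abs(sum(object@nodeEntropy) - object@totalEntropy) > 1e-9)
      msg <- c(msg, "totalEntropy does not match the sum of node entropies")
    deg <- igraph::degree(object@graph)
    if (any(object@insideCount > deg[names(object@insideCount)]))
      msg <- c(msg, "insideCount exceeds node degree")
    if (any(object@nodeEntropy < -1e-12))
      msg <- c(msg, "node entropies must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Set of (possibly overlapping) GE clusters
#'
#' Ordered result of a [runGE()] run. Each cluster records its members, the
#' seed node it was grown from, and the final graph entropy of the binary
#' split it induces. `covered` holds every node emitted in any cluster
#' before singleton exclusion, which is the set the seed selector skips.
#'
#' @slot clusters list of character vectors (sorted member names).
#' @slot seeds character, seed node of each cluster.
#' @slot finalGE numeric, final graph entropy of each cluster's split.
#' @slot mode entropy mode used.
#' @slot covered character, nodes emitted in any (pre-exclusion) cluster.
#'
#' @export
setClass("GEClusterSet",
  representation(
    clusters = "list",
    seeds = "character",
    finalGE = "numeric",
    mode = "character",
    covered = "character"
  )
)

setValidity("GEClusterSet", function(object) {
  msg <- character(0)
  k <- length(object@clusters)
  if (length(object@seeds) != k || length(object@finalGE) != k)
    msg <- c(msg, "clusters, seeds and finalGE must have equal length")
  else if (k > 0) {
    if (!all(vapply(object@clusters, is.character, logical(1))))
      msg <- c(msg, "clusters must be character vectors")
    else {
      if (!all(mapply(function(cl, s) s %in% cl, object@clusters,
                      object@seeds)))
        msg <- c(msg, "each seed must be a member of its cluster")
      if (!all(unlist(object@clusters) %in% object@covered))
        msg <- c(msg, "covered must contain every cluster member")
    }
  }
  if (length(object@mode) != 1 || !object@mode %in% .MODES)
    msg <- c(msg, "mode must be one of unweighted, ge-mw, ge-wr")
  if (length(msg)) msg else TRUE
})

#' Named reference module sets
#'
#' Gold-standard modules (protein complexes, GO term annotation groups, or
#' planted synthetic blocks) used to score predicted clusters. Construct
#' with `ReferenceSet()` from a named list, or read from a GMT file with
#' [readGMT()].
#'
#' @slot modules named list of character vectors; names are module ids.
#'
#' @export
setClass("ReferenceSet", representation(modules = "list"))

setValidity("ReferenceSet", function(object) {
  msg <- character(0)
  mods <- object@modules
  if (length(mods)) {
    if (is.null(names(mods)) || anyDuplicated(names(mods)) ||
        any(!nzchar(names(mods))))
      msg <- c(msg, "modules must have unique non-empty names")
    if (!all(vapply(mods, function(m) is.character(m) && length(m) > 0,
                    logical(1))))
      msg <- c(msg, "every module must be a non-empty character vector")
  }
  if (length(msg)) msg else TRUE
})

#' @param modules named list of character vectors (module name -> members).
#' @rdname ReferenceSet-class
#' @export
ReferenceSet <- function(modules) {
  modules <- lapply(modules, function(m) sort(unique(as.character(m))))
  new("ReferenceSet", modules = modules)
}

#' Cluster evaluation report
#'
#' Per-cluster best-match scores against a reference set plus the aggregate
#' statistics: average F-score, average precision, the percentage of
#' functionally homogeneous clusters (best precision at or above a
#' threshold), and overlap statistics over the raw cluster set. Built by
#' [evaluateClusters()].
#'
#' @slot perCluster data.frame with columns cluster, bestRefF, bestF,
#'   bestRefP, bestP.
#' @slot meanF average best F-score over the evaluated clusters.
#' @slot meanP average best precision over the evaluated clusters.
#' @slot nEvaluated number of clusters that survived filtering.
#' @slot homogeneityPct percent of evaluated clusters with best precision >=
#'   the homogeneity threshold.
#' @slot homogeneityThreshold the threshold used (default 0.6, inclusive).
#' @slot overlapNodes nodes appearing in two or more clusters.
#' @slot nOverlappingClusters clusters containing at least one such node.
#' @slot overlapPct percent of clusters that are overlapping.
#' @slot novel data.frame of proposed novel members (possibly empty).
#'
#' @export
setClass("EvaluationReport",
  representation(
    perCluster = "data.frame",
    meanF = "numeric",
    meanP = "numeric",
    nEvaluated = "integer",
    homogeneityPct = "numeric",
    homogeneityThreshold = "numeric",
    overlapNodes = "character",
    nOverlappingClusters = "integer",
    overlapPct = "numeric",
    novel = "data.frame"
  )
)

setValidity("EvaluationReport", function(object) {
  msg <- character(0)
  if (length(object@meanF) && (object@meanF < 0 || object@meanF > 1))
    msg <- c(msg, "meanF must lie in [0, 1]")
  if (length(object@meanP) && (object@meanP < 0 || object@meanP > 1))
    msg <- c(msg, "meanP must lie in [0, 1]")
  if (length(object@homogeneityPct) &&
      (object@homogeneityPct < 0 || object@homogeneityPct > 100))
    msg <- c(msg, "homogeneityPct must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})
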