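#' @rdname GEClusterSet-class
#' @param x a `GEClusterSet`.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname GEClusterSet-class
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname GEClusterSet-class
#' @export
setGeneric("clusterSeeds", function(x) standardGeneric("clusterSeeds"))

#' @rdname GEClusterSet-class
#' @export
setGeneric("clusterGE", function(x) standardGeneric("clusterGE"))

#' @rdname GEClusterSet-class
#' @export
setGeneric("entropyMode", function(x) standardGeneric("entropyMode"))

#' @rdname GEClusterSet-class
#' @export
setGeneric("coveredNodes", function(x) standardGeneric("coveredNodes"))

#' @rdname ReferenceSet-class
#' @param x a `ReferenceSet`.
#' @export
setGeneric("refModules", function(x) standardGeneric("refModules"))

#' @rdname ReferenceSet-class
#' @export
setGeneric("refNames", function(x) standardGeneric("refNames"))

#' @rdname ReferenceSet-class
#' @export
setGeneric("refUniverse", function(x) standardGeneric("refUniverse"))

setMethod("nClusters", "GEClusterSet", function(x) length(x@clusters))
setMethod("clusterMembers", "GEClusterSet", function(x) x@clusters)
setMethod("clusterSeeds", "GEClusterSet", function(x) x@seeds)
setMethod("clusterGE", "GEClusterSet", function(x) x@finalGE)
setMethod("entropyMode", "GEClusterSet", function(x) x@mode)
setMethod("coveredNodes", "GEClusterSet", function(x) x@covered)

setMethod("refModules", "ReferenceSet", function(x) x@modules)
setMethod("refNames", "ReferenceSet", function(x) names(x@modules))
setMethod("refUniverse", "ReferenceSet",
          function(x) sort(unique(unlist(x@modules, use.names = FALSE))))

setMethod("length", "ReferenceSet", function(x) length(x@modules))

setMethod("show", "GEClusterSet", function(object) {
  k <- length(object@clusters)
  cat("GEClusterSet with ", k, " clusters (mode: ", object@mode, ")\n",
      sep = "")
  if (k > 0) {
    sz <- lengths(object@clusters)
    ov <- overlapStatistics(object)
    cat(sprintf("  average cluster size: %.2f (range %d-%d)\n",
                mean(sz), min(sz), max(sz)))
    cat(sprintf("  overlapping: %d nodes, %d/%d clusters (%.1f%%)\n",
                length(ov$nodes), ov$nOverlappingClusters, k,
                ov$proportionPct))
  }
  cat(" ", length(object@covered), "nodes covered before singleton exclusion\n")
  invisible(object)
})

setMethod("show", "ReferenceSet", function(object) {
  k <- length(object@modules)
  cat("ReferenceSet with", k, "modules,",
      length(refUniverse(object)), "distinct members\n")
  if (k > 0)
    cat(sprintf("  average module size: %.2f\n",
                mean(lengths(object@modules))))
  invisible(object)
})

setMethod("show", "SeedClusterState", function(object) {
  cat("SeedClusterState (mode: ", object@mode, ")\n", sep = "")
  cat("  cluster size:", length(object@cluster), "\n")
  cat(sprintf("  total graph entropy: %.6f bits\n", object@totalEntropy))
  nz <- sum(object@nodeEntropy > 0)
  cat(" ", nz, "nodes with nonzero entropy\n")
  invisible(object)
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport over", object@nEvaluated, "clusters\n")
  cat(sprintf("  average F-score:   %.3f\n", object@meanF))
  cat(sprintf("  average precision: %.3f\n", object@meanP))
  cat(sprintf("  homogeneous clusters (P >= %.2f): %.1f%%\n",
              object@homogeneityThreshold, object@homogeneityPct))
  cat(sprintf("  overlap: %d nodes, %d clusters (%.1f%%)\n",
              length(object@overlapNodes), object@nOverlappingClusters,
              object@overlapPct))
  if (nrow(object@novel))
    cat(" ", nrow(object@novel), "clusters propose novel members\n")
  invisible(object)
})
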