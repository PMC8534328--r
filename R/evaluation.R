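# Scoring predicted clusters against reference module sets (protein
# complexes, GO annotation groups, planted blocks). For a cluster C and
# reference module r: precision = |C ∩ r| / |C|, recall = |C ∩ r| / |r|,
# F = harmonic mean. Each cluster is matched to its best reference, and the
# best scores are averaged over the clusters.

.as_cluster_list <- function(clusters) {
  if (is(clusters, "GEClusterSet")) {
    cl <- clusters@clusters
    if (length(cl)) names(cl) <- sprintf("C%04d", seq_along(cl))
    cl
  } else if (is.list(clusters)) {
    cl <- lapply(clusters, function(x) unique(as.character(x)))
    if (is.null(names(cl)) && length(cl))
      names(cl) <- sprintf("C%04d", seq_along(cl))
    cl
  } else stop("clusters must be a GEClusterSet or a list of node sets",
              call. = FALSE)
}

.as_ref_list <- function(refs) {
  if (is(refs, "ReferenceSet")) refs@modules
  else if (is.list(refs)) ReferenceSet(refs)@modules
  else stop("refs must be a ReferenceSet or a named list", call. = FALSE)
}

#' Precision, recall and F-score of one cluster against one reference
#'
#' @param cluster character vector, non-empty.
#' @param reference character vector, non-empty.
#' @return named numeric `c(precision, recall, f)`; F is 0 when the sets
#'   are disjoint.
#' @examples
#' pairScores(c("a", "b", "c"), c("b", "c", "d"))  # all 2/3
#' @export
pairScores <- function(cluster, reference) {
  cluster <- unique(as.character(cluster))
  reference <- unique(as.character(reference))
  if (length(cluster) == 0 || length(reference) == 0)
    stop("validation error: empty cluster or reference", call. = FALSE)
  ov <- length(intersect(cluster, reference))
  p <- ov / length(cluster)
  r <- ov / length(reference)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f = f)
}

# Best-match table: for each cluster the maximum F and maximum P over all
# references, with ties broken by reference name for determinism.
.best_scores <- function(clusters, refs) {
  cl <- .as_cluster_list(clusters)
  rf <- .as_ref_list(refs)
  rnames <- names(rf)
  ro <- order(rnames, method = "radix")
  rf <- rf[ro]; rnames <- rnames[ro]
  rlen <- lengths(rf)
  res <- lapply(seq_along(cl), function(i) {
    cset <- cl[[i]]
    ov <- vapply(rf, function(r) length(intersect(cset, r)), numeric(1))
    p <- ov / length(cset)
    r <- ov / rlen
    f <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
    bi_f <- which.max(f)   # first max = lexicographically smallest name
    bi_p <- which.max(p)
    data.frame(cluster = names(cl)[i],
               bestRefF = rnames[bi_f], bestF = f[bi_f],
               bestRefP = rnames[bi_p], bestP = p[bi_p],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Restrict clusters and references to a common evaluable universe
#'
#' Applies the two evaluation filters: reference members absent from the
#' network are removed from the references, and cluster members absent
#' from the (filtered) reference universe are removed from the clusters.
#' Modules or clusters emptied by filtering are dropped entirely.
#'
#' @param clusters a [GEClusterSet-class] or list of node sets.
#' @param graph the `igraph` the clusters were computed on.
#' @param refs a [ReferenceSet-class] or named list.
#' @return `list(clusters = <named list>, refs = <ReferenceSet>)`.
#' @export
filterForEvaluation <- function(clusters, graph, refs) {
  stopifnot(inherits(graph, "igraph"))
  cl <- .as_cluster_list(clusters)
  rf <- .as_ref_list(refs)
  nodes <- igraph::V(graph)$name
  rf <- lapply(rf, function(r) intersect(r, nodes))
  rf <- rf[lengths(rf) > 0]
  universe <- unique(unlist(rf, use.names = FALSE))
  cl <- lapply(cl, function(x) intersect(x, universe))
  cl <- cl[lengths(cl) > 0]
  list(clusters = cl,
       refs = if (length(rf)) ReferenceSet(rf) else
         new("ReferenceSet", modules = list()))
}

#' Average best F-score over clusters
#'
#' For each cluster, the maximum F-score over all reference modules; the
#' mean of these maxima. Filtering (see [filterForEvaluation()]) is the
#' caller's responsibility.
#'
#' @param clusters a [GEClusterSet-class] or list of node sets (non-empty).
#' @param refs a [ReferenceSet-class] or named list.
#' @return the average F-score in \[0, 1\].
#' @export
averageFscore <- function(clusters, refs) {
  cl <- .as_cluster_list(clusters)
  if (length(cl) == 0)
    stop("undefined result: no scorable clusters", call. = FALSE)
  mean(.best_scores(cl, refs)$bestF)
}

#' Average best precision over clusters
#'
#' @inheritParams averageFscore
#' @return the average precision in \[0, 1\].
#' @export
averagePrecision <- function(clusters, refs) {
  cl <- .as_cluster_list(clusters)
  if (length(cl) == 0)
    stop("undefined result: no scorable clusters", call. = FALSE)
  mean(.best_scores(cl, refs)$bestP)
}

#' Proportion of functionally homogeneous clusters
#'
#' Percent of clusters whose best precision against the references is at
#' least `threshold` (inclusive; 0.6 by default). A cluster meeting the
#' bar draws most of its members from a single reference module.
#'
#' @inheritParams averageFscore
#' @param threshold precision cutoff in \[0, 1\] (default 0.6).
#' @return a percentage in \[0, 100\].
#' @export
homogeneityProportion <- function(clusters, refs, threshold = 0.6) {
  cl <- .as_cluster_list(clusters)
  if (length(cl) == 0)
    stop("undefined result: no scorable clusters", call. = FALSE)
  bp <- .best_scores(cl, refs)$bestP
  100 * mean(bp >= threshold)
}

#' Overlap statistics of a cluster set
#'
#' A node appearing in two or more clusters is an overlapping node; a
#' cluster containing at least one overlapping node is an overlapping
#' cluster. Computed on the raw cluster set, before any reference
#' filtering; invariant to cluster order.
#'
#' @param clusters a [GEClusterSet-class] or list of node sets.
#' @return `list(nodes, nOverlappingClusters, proportionPct)`.
#' @export
overlapStatistics <- function(clusters) {
  cl <- .as_cluster_list(clusters)
  if (length(cl) == 0)
    return(list(nodes = character(0), nOverlappingClusters = 0L,
                proportionPct = 0))
  cl <- lapply(cl, unique)
  freq <- table(unlist(cl, use.names = FALSE))
  ovn <- sort(names(freq)[freq >= 2])
  ovc <- sum(vapply(cl, function(x) any(x %in% ovn), logical(1)))
  list(nodes = ovn, nOverlappingClusters = as.integer(ovc),
       proportionPct = 100 * ovc / length(cl))
}

#' Propose novel members of reference modules
#'
#' Matches each cluster against unfiltered references (members absent from
#' the network are deliberately kept, so a cluster can "complete" a
#' module). Clusters whose best F-score strictly exceeds `fThreshold`
#' (default 0.9) are reported together with their members missing from the
#' matched reference -- the candidate novel members.
#'
#' @param clusters a [GEClusterSet-class] or list of node sets.
#' @param refs a [ReferenceSet-class], NOT filtered against the graph.
#' @param fThreshold F-score cutoff, exclusive (default 0.9).
#' @return data.frame with columns cluster, reference, f, novel
#'   (comma-separated candidate names, possibly empty).
#' @export
proposeNovelMembers <- function(clusters, refs, fThreshold = 0.9) {
  cl <- .as_cluster_list(clusters)
  rf <- .as_ref_list(refs)
  if (length(cl) == 0 || length(rf) == 0)
    return(data.frame(cluster = character(0), reference = character(0),
                      f = numeric(0), novel = character(0),
                      stringsAsFactors = FALSE))
  bs <- .best_scores(cl, rf)
  hit <- bs$bestF > fThreshold
  out <- lapply(which(hit), function(i) {
    rname <- bs$bestRefF[i]
    novel <- sort(setdiff(cl[[bs$cluster[i]]], rf[[rname]]))
    data.frame(cluster = bs$cluster[i], reference = rname, f = bs$bestF[i],
               novel = paste(novel, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
  else data.frame(cluster = character(0), reference = character(0),
                  f = numeric(0), novel = character(0),
                  stringsAsFactors = FALSE)
}

#' Full cluster evaluation against a reference set
#'
#' Applies the evaluation filters, computes per-cluster best matches, the
#' average F-score and precision, the homogeneous-cluster percentage, and
#' overlap statistics (the latter on the raw, unfiltered cluster set).
#' Optionally proposes novel members against the unfiltered references.
#'
#' @param clusterSet a [GEClusterSet-class] or list of node sets.
#' @param graph the `igraph` the clusters came from.
#' @param refs a [ReferenceSet-class] or named list.
#' @param homogeneityThreshold precision cutoff for homogeneity
#'   (default 0.6, inclusive).
#' @param novelFThreshold if non-`NULL`, also run [proposeNovelMembers()]
#'   with this (exclusive) F cutoff.
#' @return an [EvaluationReport-class].
#' @export
evaluateClusters <- function(clusterSet, graph, refs,
                             homogeneityThreshold = 0.6,
                             novelFThreshold = NULL) {
  flt <- filterForEvaluation(clusterSet, graph, refs)
  if (length(flt$clusters) == 0)
    stop("undefined result: no scorable clusters after filtering",
         call. = FALSE)
  bs <- .best_scores(flt$clusters, flt$refs)
  ov <- overlapStatistics(clusterSet)
  novel <- if (is.null(novelFThreshold))
    data.frame(cluster = character(0), reference = character(0),
               f = numeric(0), novel = character(0),
               stringsAsFactors = FALSE)
  else proposeNovelMembers(clusterSet, refs, novelFThreshold)
  new("EvaluationReport",
      perCluster = bs,
      meanF = mean(bs$bestF),
      meanP = mean(bs$bestP),
      nEvaluated = nrow(bs),
      homogeneityPct = 100 * mean(bs$bestP >= homogeneityThreshold),
      homogeneityThreshold = homogeneityThreshold,
      overlapNodes = ov$nodes,
      nOverlappingClusters = ov$nOverlappingClusters,
      overlapPct = ov$proportionPct,
      novel = novel)
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member identifiers. Members
#' are upper-cased to match the canonical network node names.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("parse error: GMT line ", bad[1],
         " has fewer than 3 fields", call. = FALSE)
  out <- lapply(parts, function(p) sort(unique(toupper(p[-(1:2)]))))
  names(out) <- vapply(parts, `[[`, character(1), 1L)
  out
}

#' Write named node sets in GMT format
#'
#' @param sets named list of character vectors, or a [ReferenceSet-class].
#' @param path output file path.
#' @param description second-column text (recycled; default `"NA"`).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, description = "NA") {
  if (is(sets, "ReferenceSet")) sets <- sets@modules
  writeLines(sprintf("%s\t%s\t%s", names(sets),
                     rep_len(description, length(sets)),
                     vapply(sets, paste, character(1), collapse = "\t")),
             path)
  invisible(path)
}

#' Write an evaluation report to disk
#'
#' Emits a per-cluster TSV (`<prefix>.percluster.tsv`), a human-readable
#' summary block (`<prefix>.summary.txt`), a machine-readable JSON summary
#' (`<prefix>.summary.json`), and, when novel members were proposed, a
#' `<prefix>.novel.tsv` table.
#'
#' @param report an [EvaluationReport-class].
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
writeEvaluationReport <- function(report, prefix) {
  stopifnot(is(report, "EvaluationReport"))
  files <- character(0)
  f1 <- paste0(prefix, ".percluster.tsv")
  utils::write.table(report@perCluster, f1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f1)
  f2 <- paste0(prefix, ".summary.txt")
  writeLines(c(
    sprintf("clusters_evaluated\t%d", report@nEvaluated),
    sprintf("mean_f\t%.6f", report@meanF),
    sprintf("mean_p\t%.6f", report@meanP),
    sprintf("homogeneity_pct\t%.3f", report@homogeneityPct),
    sprintf("overlapping_nodes\t%d", length(report@overlapNodes)),
    sprintf("overlapping_clusters\t%d", report@nOverlappingClusters),
    sprintf("overlap_pct\t%.3f", report@overlapPct)), f2)
  files <- c(files, f2)
  f3 <- paste0(prefix, ".summary.json")
  jsonlite::write_json(list(
    clusters_evaluated = report@nEvaluated,
    mean_f = report@meanF,
    mean_p = report@meanP,
    homogeneity_pct = report@homogeneityPct,
    overlapping_nodes = length(report@overlapNodes),
    overlapping_clusters = report@nOverlappingClusters,
    overlap_pct = report@overlapPct), f3, auto_unbox = TRUE, digits = NA)
  files <- c(files, f3)
  if (nrow(report@novel)) {
    f4 <- paste0(prefix, ".novel.tsv")
    utils::write.table(report@novel, f4, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f4)
  }
  invisible(files)
}
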