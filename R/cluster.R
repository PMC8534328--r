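# The seed-growth GE clustering procedure:
#   1. among uncovered nodes, pick the highest-degree one as seed
#   2. initial cluster = seed + its neighbors
#   3. prune: visit the seed's neighbors once, highest degree first, and
#      remove each iff GE strictly decreases (the seed itself never leaves)
#   4. grow: sweep over the cluster's outside neighbors, highest degree
#      first, adding each iff GE strictly decreases; repeat to a fixpoint
#      (nodes pruned in step 3 may be re-added)
#   5. emit the cluster at its reached GE minimum
#   6. mark all emitted members covered and repeat until no seed remains
# Clusters from different seeds may overlap; singletons are marked covered
# (so the loop terminates) but excluded from the output.

.prune_internal <- function(idx, st, seed_i, mode) {
  nb <- idx$adj[[seed_i]]
  if (!length(nb)) return(invisible(st))
  for (u in .order_by_degree(idx, nb)) {
    if (!st$inC[u]) next
    if (.delta_move(idx, st, u, add = FALSE, mode) < -.GE_TOL)
      .apply_move(idx, st, u, add = FALSE, mode)
  }
  invisible(st)
}

.growth_internal <- function(idx, st, mode) {
  for (sweep in seq_len(idx$n)) {
    cand <- which(st$m > 0L & !st$inC)
    if (!length(cand)) break
    added <- FALSE
    for (u in .order_by_degree(idx, cand)) {
      if (.delta_move(idx, st, u, add = TRUE, mode) < -.GE_TOL) {
        .apply_move(idx, st, u, add = TRUE, mode)
        added <- TRUE
      }
    }
    if (!added) break
  }
  invisible(st)
}

#' Select the next seed node
#'
#' Returns the uncovered node of highest degree (unweighted edge count;
#' weights never influence seeding), ties broken by node name, or `NULL`
#' when every node is covered and the clustering loop must stop.
#'
#' @param graph an `igraph` object.
#' @param covered character vector of already-covered node names.
#' @return a node name, or `NULL`.
#' @export
selectSeed <- function(graph, covered = character(0)) {
  stopifnot(inherits(graph, "igraph"))
  idx <- .graph_index(graph)
  unc <- which(!idx$names %in% toupper(covered))
  if (!length(unc)) return(NULL)
  idx$names[.order_by_degree(idx, unc)[1]]
}

#' Initial seed cluster: the seed's closed neighborhood
#'
#' @param graph an `igraph` object.
#' @param seed a node name.
#' @return character vector `{seed} U N(seed)`, sorted.
#' @export
initSeedCluster <- function(graph, seed) {
  stopifnot(inherits(graph, "igraph"))
  seed <- toupper(as.character(seed)[1])
  if (!seed %in% igraph::V(graph)$name)
    stop("seed '", seed, "' is not in the graph", call. = FALSE)
  sort(unique(c(seed, names(igraph::neighbors(graph, seed)))))
}

#' Prune phase of the seed-growth procedure
#'
#' Visits each neighbor of the seed exactly once, in descending order of
#' degree (ties by name), and removes it from the cluster iff that strictly
#' decreases graph entropy. The seed is never removed, and GE is
#' non-increasing across the phase.
#'
#' @param graph the `igraph` the state was built on.
#' @param state a [SeedClusterState-class] over the initial seed cluster.
#' @param seed the seed node name.
#' @return the updated [SeedClusterState-class].
#' @export
prunePhase <- function(graph, state, seed) {
  stopifnot(is(state, "SeedClusterState"))
  seed <- toupper(as.character(seed)[1])
  env <- .state_from_s4(state)
  seed_i <- match(seed, env$idx$names)
  if (is.na(seed_i))
    stop("seed '", seed, "' is not in the graph", call. = FALSE)
  .prune_internal(env$idx, env$st, seed_i, state@mode)
  .state_to_s4(state@graph, env$idx, env$st, state@mode)
}

#' Growth phase of the seed-growth procedure
#'
#' Repeatedly sweeps over the cluster's outside neighbors (nodes linked to
#' any member), highest degree first, adding each iff that strictly
#' decreases graph entropy, until a full sweep adds nothing. Nodes removed
#' during [prunePhase()] are eligible for re-addition.
#'
#' @inheritParams prunePhase
#' @return the updated [SeedClusterState-class].
#' @export
growthPhase <- function(graph, state) {
  stopifnot(is(state, "SeedClusterState"))
  env <- .state_from_s4(state)
  .growth_internal(env$idx, env$st, state@mode)
  .state_to_s4(state@graph, env$idx, env$st, state@mode)
}

#' Run graph-entropy seed-growth clustering
#'
#' Iterates seed selection, neighborhood initialization, pruning and growth
#' until every node has been covered by some emitted cluster, then drops
#' clusters smaller than `minClusterSize` (singleton exclusion by default).
#' The procedure is fully deterministic: identical inputs give identical
#' cluster sets, member for member and order for order.
#'
#' @param graph a canonical `igraph` (see [readEdgeList()]).
#' @param mode entropy mode: `"unweighted"` (edge counts only), `"ge-mw"`
#'   (entropy terms multiplied by inside/outside weight sums), or
#'   `"ge-wr"` (weight-sum ratios; the variant recommended for weighted
#'   networks).
#' @param minClusterSize smallest cluster to keep (default 2).
#' @return a [GEClusterSet-class].
#' @examples
#' g <- makeCliqueUnion(c(5, 6, 4))$graph
#' cs <- runGE(g)
#' nClusters(cs)   # 3, one per clique
#' clusterGE(cs)   # all 0: cliques are perfectly modular
#' @export
runGE <- function(graph, mode = "unweighted", minClusterSize = 2) {
  stopifnot(inherits(graph, "igraph"))
  mode <- .norm_mode(mode)
  idx <- .graph_index(graph)
  clusters <- list()
  seeds <- character(0)
  ges <- numeric(0)
  covered <- logical(idx$n)
  while (any(!covered)) {
    unc <- which(!covered)
    seed_i <- .order_by_degree(idx, unc)[1]
    members0 <- c(seed_i, idx$adj[[seed_i]])
    st <- .state_init(idx, members0, mode)
    .prune_internal(idx, st, seed_i, mode)
    .growth_internal(idx, st, mode)
    mem <- which(st$inC)
    covered[mem] <- TRUE
    if (length(mem) >= minClusterSize) {
      clusters[[length(clusters) + 1L]] <- sort(idx$names[mem])
      seeds <- c(seeds, idx$names[seed_i])
      ges <- c(ges, st$total)
    }
  }
  new("GEClusterSet", clusters = clusters, seeds = seeds, finalGE = ges,
      mode = mode, covered = sort(idx$names[covered]))
}

#' Write clusters as a TSV table
#'
#' One cluster per line: `cluster_id`, seed, final GE, then the member
#' names, all tab-separated. A `#mode=` header line records the entropy
#' mode for round-tripping with [readClustersTSV()].
#'
#' @param clusterSet a [GEClusterSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeClustersTSV <- function(clusterSet, path) {
  stopifnot(is(clusterSet, "GEClusterSet"))
  lines <- sprintf("C%04d\t%s\t%s\t%s",
                   seq_along(clusterSet@clusters),
                   clusterSet@seeds,
                   formatC(clusterSet@finalGE, digits = 17, format = "g"),
                   vapply(clusterSet@clusters, paste, character(1),
                          collapse = "\t"))
  writeLines(c(paste0("#mode=", clusterSet@mode), lines), path)
  invisible(path)
}

#' Read clusters written by [writeClustersTSV()]
#'
#' @param path path to the TSV cluster file.
#' @return a [GEClusterSet-class].
#' @export
readClustersTSV <- function(path) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  mode <- "unweighted"
  mline <- grep("^#mode=", lines)
  if (length(mline)) mode <- sub("^#mode=", "", lines[mline[1]])
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4)
  if (length(bad))
    stop("parse error: cluster line ", bad[1], " has fewer than 4 fields",
         call. = FALSE)
  clusters <- lapply(parts, function(p) sort(unique(p[-(1:3)])))
  seeds <- vapply(parts, `[[`, character(1), 2L)
  ges <- as.numeric(vapply(parts, `[[`, character(1), 3L))
  new("GEClusterSet", clusters = clusters, seeds = seeds, finalGE = ges,
      mode = .norm_mode(mode),
      covered = sort(unique(unlist(clusters, use.names = FALSE))))
}

#' Write clusters in GMT format
#'
#' `cluster_id TAB GE TAB member...` per line, compatible with the
#' reference-set reader [readGMT()].
#'
#' @inheritParams writeClustersTSV
#' @return `path`, invisibly.
#' @export
writeClustersGMT <- function(clusterSet, path) {
  stopifnot(is(clusterSet, "GEClusterSet"))
  writeLines(sprintf("C%04d\tGE\t%s",
                     seq_along(clusterSet@clusters),
                     vapply(clusterSet@clusters, paste, character(1),
                            collapse = "\t")),
             path)
  invisible(path)
}
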