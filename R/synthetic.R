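# Seeded synthetic networks with known ground truth. All three generators
# emit canonical graphs (upper-case names, no self-loops or duplicates,
# weight 1.0) plus, where blocks exist, a ReferenceSet of the planted
# modules. A single seeded RNG drives each call and the seed is recorded as
# the graph attribute `rng_seed`, so the same seed reproduces the same
# edge-list bytes.

.node_names <- function(n) sprintf("V%0*d", max(3L, nchar(n)), seq_len(n))

# Block layout shared by the clique-union and planted-partition generators:
# consecutive blocks share `overlap` members of a common node pool.
.block_layout <- function(sizes, overlap = 0L) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1 || any(sizes < 2))
    stop("validation error: every block size must be >= 2", call. = FALSE)
  overlap <- as.integer(overlap)
  if (overlap < 0 || (length(sizes) > 1 && overlap >= min(sizes)))
    stop("validation error: overlap_nodes must be in [0, min(sizes) - 1]",
         call. = FALSE)
  n <- sum(sizes) - overlap * (length(sizes) - 1L)
  nm <- .node_names(n)
  starts <- cumsum(c(1L, head(sizes, -1) - overlap))
  blocks <- lapply(seq_along(sizes), function(b)
    seq.int(starts[b], length.out = sizes[b]))
  names(blocks) <- sprintf("BLOCK%02d", seq_along(sizes))
  list(n = n, names = nm, blocks = blocks)
}

.graph_from_pairs <- function(i, j, names, seed = NULL) {
  d <- data.frame(from = names[i], to = names[j],
                  weight = rep(1.0, length(i)), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(d, directed = FALSE, vertices = names)
  if (!is.null(seed)) g <- igraph::set_graph_attr(g, "rng_seed", seed)
  g
}

#' Disjoint-clique benchmark network
#'
#' A union of disjoint cliques of the given sizes; the reference modules
#' are the cliques themselves. Since no edge crosses a block boundary,
#' the planted partition has graph entropy 0 and a correct clustering
#' recovers every clique exactly.
#'
#' @param sizes integer vector of clique sizes (each >= 2).
#' @param seed optional integer recorded as `rng_seed` (the construction
#'   itself is deterministic).
#' @return `list(graph = <igraph>, references = <ReferenceSet>)`.
#' @examples
#' cu <- makeCliqueUnion(c(5, 6, 4))
#' igraph::ecount(cu$graph)  # 10 + 15 + 6 = 31
#' @export
makeCliqueUnion <- function(sizes, seed = NULL) {
  lay <- .block_layout(sizes, overlap = 0L)
  pairs <- do.call(rbind, lapply(lay$blocks, function(b)
    t(utils::combn(b, 2))))
  g <- .graph_from_pairs(pairs[, 1], pairs[, 2], lay$names, seed)
  list(graph = g,
       references = ReferenceSet(lapply(lay$blocks,
                                        function(b) lay$names[b])))
}

#' Planted-partition benchmark network
#'
#' Nodes are organized into blocks; consecutive blocks may share
#' `overlapNodes` members. Any node pair sharing at least one block is
#' connected with probability `pIn`, all other pairs with probability
#' `pOut`. With `pIn = 1`, `pOut = 0` and no overlap this reduces exactly
#' to [makeCliqueUnion()]. References are the planted blocks.
#'
#' @param sizes integer vector of block sizes (each >= 2).
#' @param pIn within-block edge probability.
#' @param pOut cross-block edge probability (`0 <= pOut <= pIn <= 1`).
#' @param overlapNodes members shared between consecutive blocks
#'   (default 0).
#' @param seed integer RNG seed; fixed seed gives a byte-identical network.
#' @return `list(graph = <igraph>, references = <ReferenceSet>)`.
#' @export
makePlantedPartition <- function(sizes, pIn, pOut, overlapNodes = 0,
                                 seed = 1) {
  if (!is.finite(pIn) || !is.finite(pOut) || pOut < 0 || pIn > 1 ||
      pOut > pIn)
    stop("validation error: need 0 <= pOut <= pIn <= 1", call. = FALSE)
  lay <- .block_layout(sizes, overlapNodes)
  n <- lay$n
  # within = pair shares at least one block
  memb <- matrix(FALSE, n, length(lay$blocks))
  for (b in seq_along(lay$blocks)) memb[lay$blocks[[b]], b] <- TRUE
  co <- tcrossprod(memb)            # co-membership counts
  ut <- upper.tri(co)
  within <- co[ut] > 0
  ii <- row(co)[ut]
  jj <- col(co)[ut]
  set.seed(seed)
  u <- runif(length(within))
  keep <- u < ifelse(within, pIn, pOut)
  g <- .graph_from_pairs(ii[keep], jj[keep], lay$names, seed)
  list(graph = g,
       references = ReferenceSet(lapply(lay$blocks,
                                        function(b) lay$names[b])))
}

# Map linear pair indices (colex order: index(i,j) = C(j-1,2) + i with
# i < j) back to pairs; used to sample exactly m distinct edges.
.pair_from_index <- function(k, n) {
  j <- floor((3 + sqrt(8 * k - 7)) / 2)
  base <- (j - 1) * (j - 2) / 2
  dn <- base >= k
  j[dn] <- j[dn] - 1
  base <- (j - 1) * (j - 2) / 2
  up <- k > base + (j - 1)
  j[up] <- j[up] + 1
  base <- (j - 1) * (j - 2) / 2
  cbind(i = k - base, j = j)
}

#' Erdős–Rényi random graph with a fixed edge count
#'
#' A uniform simple graph on `n` nodes with exactly `m` edges, sampled
#' without replacement from all node pairs: the null model matching a real
#' network's node and edge counts while destroying its modular structure.
#'
#' @param n number of nodes.
#' @param m number of edges (`m <= n(n-1)/2`).
#' @param seed integer RNG seed.
#' @return an `igraph` object.
#' @export
makeERRandom <- function(n, m, seed = 1) {
  n <- as.integer(n)
  m <- as.integer(m)
  total <- n * (n - 1) / 2
  if (m < 0 || m > total)
    stop("validation error: m must be in [0, n(n-1)/2]", call. = FALSE)
  nm <- .node_names(n)
  if (m == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, n, name = nm)
    return(igraph::set_graph_attr(g, "rng_seed", seed))
  }
  set.seed(seed)
  ks <- sample.int(total, m)
  pr <- .pair_from_index(ks, n)
  .graph_from_pairs(pr[, 1], pr[, 2], nm, seed)
}
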