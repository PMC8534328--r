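# Entropy math: k-way partition entropy, binary seed-cluster entropy in
# the three modes, full-state computation and incremental move deltas.

test_that("partition node entropy matches hand-computed edge splits", {
  star <- g_from_edges(c("S A", "S B", "S C", "S D"))
  p <- list(c("S", "A", "B"), c("C", "D"))
  expect_equal(nodeEntropyPartition(star, "S", p), 1.0)       # 2/2 split
  expect_equal(nodeEntropyPartition(star, "A", p), 0.0)       # all one side

  y <- g_from_edges(c("V A", "V B", "V C"))
  p3 <- list(c("V", "A"), "B", "C")
  expect_equal(nodeEntropyPartition(y, "V", p3), log2(3))     # 1/1/1
  expect_error(nodeEntropyPartition(y, "Z", p3), "not in the graph")
})

test_that("partition graph entropy: modular partitions score 0", {
  g <- g_from_edges(c(clique_edges(c("A", "B", "C")),
                      clique_edges(c("X", "Y", "Z"))))
  expect_equal(graphEntropyPartition(
    g, list(c("A", "B", "C"), c("X", "Y", "Z"))), 0.0)
  # one-subgraph partition is always 0
  expect_equal(graphEntropyPartition(g, list(igraph::V(g)$name)), 0.0)

  path <- g_from_edges(c("A B", "B C"))
  expect_equal(graphEntropyPartition(path, list(c("A", "B"), "C")), 1.0)
  expect_error(graphEntropyPartition(path, list(c("A", "B"), c("B", "C"))),
               "disjoint")
})

test_that("binary node entropy: unweighted, GE-MW and GE-WR hand values", {
  path <- g_from_edges(c("A B", "B C"))
  expect_equal(nodeEntropyBinary(path, "B", c("A", "B")), 1.0)
  expect_equal(nodeEntropyBinary(path, "A", c("A", "B")), 0.0)
  expect_equal(nodeEntropyBinary(path, "C", c("A", "B")), 0.0)

  # v with inside weights {0.8, 0.2}, outside weight {0.5}:
  # Wi = 1.0, Wo = 0.5, p_i = 2/3
  g <- g_from_edges(c("V A 0.8", "V B 0.2", "V C 0.5"), hasWeights = TRUE)
  cl <- c("V", "A", "B")
  mw <- -1.0 * (2 / 3) * log2(2 / 3) - 0.5 * (1 / 3) * log2(1 / 3)
  expect_equal(nodeEntropyBinary(g, "V", cl, "ge-mw"), mw)     # ~0.654
  wr <- -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3)
  expect_equal(nodeEntropyBinary(g, "V", cl, "ge-wr"), wr)     # ~0.918
})

test_that("GE-WR equals unweighted entropy under any constant weight", {
  for (s in 1:15) {
    g <- makeERRandom(10, sample(8:20, 1), seed = s)
    const <- runif(1, 0.1, 5)
    g <- igraph::set_edge_attr(g, "weight",
                               value = rep(const, igraph::ecount(g)))
    nodes <- igraph::V(g)$name
    cl <- sample(nodes, sample(2:8, 1))
    for (v in sample(nodes, 4)) {
      expect_equal(nodeEntropyBinary(g, v, cl, "ge-wr"),
                   nodeEntropyBinary(g, v, cl, "unweighted"),
                   tolerance = 1e-12)
    }
  }
})

test_that("clusterEntropy totals match hand computation and oracle", {
  k5 <- g_from_edges(clique_edges(paste0("N", 1:5)))
  expect_equal(clusterEntropy(k5, paste0("N", 1:5))@totalEntropy, 0.0)

  path <- g_from_edges(c("A B", "B C"))
  expect_equal(clusterEntropy(path, c("A", "B"))@totalEntropy, 1.0)

  k4 <- g_from_edges(clique_edges(LETTERS[1:4]))
  st <- clusterEntropy(k4, c("A", "B", "C"))
  h23 <- -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3)
  expect_equal(st@totalEntropy, 3 * h23)                       # ~2.755
  expect_equal(unname(st@nodeEntropy["D"]), 0.0)

  expect_error(clusterEntropy(path, character(0)), "non-empty")
})

test_that("SeedClusterState invariants hold on random instances", {
  for (s in 1:10) {
    g <- makeERRandom(12, 24, seed = s)
    cl <- sample(igraph::V(g)$name, 5)
    for (mode in c("unweighted", "ge-mw", "ge-wr")) {
      st <- clusterEntropy(g, cl, mode)
      expect_equal(sum(st@nodeEntropy), st@totalEntropy, tolerance = 1e-9)
      expect_true(all(st@nodeEntropy >= 0))
      deg <- igraph::degree(g)
      expect_true(all(st@insideCount <= deg[names(st@insideCount)]))
      # nodes with all edges on one side have zero entropy
      one_side <- st@insideCount == 0 | st@insideCount == deg
      expect_true(all(st@nodeEntropy[one_side] == 0))
      if (mode != "ge-mw")
        expect_true(all(st@nodeEntropy <= 1 + 1e-12))
    }
  }
})

test_that("incremental deltas agree with full recomputation in all modes", {
  set.seed(7)
  for (trial in 1:60) {
    n <- sample(5:12, 1)
    mmax <- n * (n - 1) / 2
    g <- makeERRandom(n, sample(4:mmax, 1), seed = trial)
    g <- igraph::set_edge_attr(
      g, "weight", value = round(runif(igraph::ecount(g), 0.1, 1), 3))
    nodes <- igraph::V(g)$name
    cl <- sample(nodes, sample(1:(n - 1), 1))
    out <- setdiff(nodes, cl)
    for (mode in c("unweighted", "ge-mw", "ge-wr")) {
      st <- clusterEntropy(g, cl, mode)
      v_add <- sample(out, 1)
      d <- deltaEntropyMove(st, v_add, "add")
      expect_equal(d, oracle_cluster_entropy(g, c(cl, v_add), mode) -
                     oracle_cluster_entropy(g, cl, mode), tolerance = 1e-9)
      if (length(cl) > 1) {
        v_rem <- sample(cl, 1)
        d2 <- deltaEntropyMove(st, v_rem, "remove")
        expect_equal(d2, oracle_cluster_entropy(g, setdiff(cl, v_rem), mode) -
                       oracle_cluster_entropy(g, cl, mode), tolerance = 1e-9)
      }
    }
  }
})

test_that("a move followed by its reverse nets to zero", {
  g <- makeERRandom(10, 18, seed = 2)
  cl <- igraph::V(g)$name[1:4]
  st <- clusterEntropy(g, cl, "unweighted")
  v <- setdiff(igraph::V(g)$name, cl)[1]
  d_add <- deltaEntropyMove(st, v, "add")
  st2 <- clusterEntropy(g, c(cl, v), "unweighted")
  d_back <- deltaEntropyMove(st2, v, "remove")
  expect_equal(d_add + d_back, 0, tolerance = 1e-9)
})

test_that("delta queries enforce membership direction", {
  path <- g_from_edges(c("A B", "B C"))
  st <- clusterEntropy(path, c("A", "B"))
  expect_equal(deltaEntropyMove(st, "C", "add"), -1.0)
  expect_error(deltaEntropyMove(st, "A", "add"), "already a cluster member")
  expect_error(deltaEntropyMove(st, "C", "remove"), "not a cluster member")
  expect_error(deltaEntropyMove(st, "Z", "add"), "not in the graph")
  # querying does not mutate the state
  expect_equal(st@totalEntropy, 1.0)
  expect_setequal(st@cluster, c("A", "B"))
})
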