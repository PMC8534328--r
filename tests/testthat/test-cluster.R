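# The six-step seed-growth procedure.

test_that("seed selection: highest degree, lexicographic ties, coverage", {
  g <- g_from_edges(c("A B", "A C", "A D", "B C", "B D", "E C"))
  # A and B both have degree 3: lexicographic tie-break picks A
  expect_equal(unname(igraph::degree(g, c("A", "B"))), c(3, 3))
  expect_equal(selectSeed(g), "A")
  expect_equal(selectSeed(g, covered = "A"), "B")
  expect_null(selectSeed(g, covered = igraph::V(g)$name))
})

test_that("initial seed cluster is the closed neighborhood", {
  star <- g_from_edges(c("S A", "S B", "S C", "S D"))
  expect_setequal(initSeedCluster(star, "S"), c("S", "A", "B", "C", "D"))
  expect_setequal(initSeedCluster(star, "A"), c("A", "S"))
  k4 <- g_from_edges(clique_edges(LETTERS[1:4]))
  expect_setequal(initSeedCluster(k4, "B"), LETTERS[1:4])
  expect_error(initSeedCluster(k4, "Z"), "not in the graph")
})

test_that("prune keeps cohesive members and removes stragglers", {
  # K5: removing any member of the full clique raises GE
  k5 <- g_from_edges(clique_edges(paste0("N", 1:5)))
  st <- clusterEntropy(k5, initSeedCluster(k5, "N1"))
  expect_true(deltaEntropyMove(st, "N2", "remove") > 0)
  st2 <- prunePhase(k5, st, "N1")
  expect_setequal(st2@cluster, paste0("N", 1:5))

  # K4 {S,A,B,C} plus straggler V: S-V and V tied into an outside
  # triangle F,G,H. With V inside, e(V) = H2(1/4) and each of F,G,H is
  # mixed at H2(1/3); cutting V zeroes F,G,H and costs only e(S) = H2(3/4):
  # delta = H2(3/4) - 3*H2(1/3) < 0, so the prune pass removes V.
  g <- g_from_edges(c(clique_edges(c("S", "A", "B", "C")), "S V",
                      "V F", "V G", "V H", "F G", "G H", "F H"))
  st3 <- prunePhase(g, clusterEntropy(g, initSeedCluster(g, "S")), "S")
  expect_setequal(st3@cluster, c("S", "A", "B", "C"))
  h2 <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(st3@totalEntropy, h2(3 / 4) + h2(1 / 4))
})

test_that("growth adds entropy-reducing neighbors to a fixpoint", {
  path <- g_from_edges(c("A B", "B C"))
  st <- growthPhase(path, clusterEntropy(path, c("A", "B")))
  expect_setequal(st@cluster, c("A", "B", "C"))
  expect_equal(st@totalEntropy, 0.0)

  # two K5s connected by a single bridge edge: the far clique stays out
  g <- g_from_edges(c(clique_edges(paste0("A", 1:5)),
                      clique_edges(paste0("B", 1:5)), "A1 B1"))
  st2 <- growthPhase(g, clusterEntropy(g, paste0("A", 1:5)))
  expect_setequal(st2@cluster, paste0("A", 1:5))
})

test_that("prune and growth never increase graph entropy", {
  for (s in 1:8) {
    g <- makeERRandom(15, 35, seed = s + 50)
    seed <- selectSeed(g)
    st0 <- clusterEntropy(g, initSeedCluster(g, seed))
    st1 <- prunePhase(g, st0, seed)
    st2 <- growthPhase(g, st1)
    expect_lte(st1@totalEntropy, st0@totalEntropy + 1e-12)
    expect_lte(st2@totalEntropy, st1@totalEntropy + 1e-12)
  }
})

test_that("disjoint cliques are recovered exactly in every mode", {
  cu <- makeCliqueUnion(c(5, 6, 4))
  for (mode in c("unweighted", "ge-mw", "ge-wr")) {
    cs <- runGE(cu$graph, mode = mode)
    expect_equal(nClusters(cs), 3)
    got <- clusterMembers(cs)
    expect_setequal(
      vapply(got, paste, character(1), collapse = ","),
      vapply(refModules(cu$references), paste, character(1), collapse = ","))
    expect_equal(clusterGE(cs), rep(0.0, 3))
  }
})

test_that("singletons are excluded but still cover their seeds", {
  g <- makeERRandom(10, 0, seed = 1)
  cs <- runGE(g)
  expect_equal(nClusters(cs), 0)
  expect_equal(length(coveredNodes(cs)), 10)   # termination guarantee
})

test_that("a path collapses into one zero-entropy cluster", {
  cs <- runGE(g_from_edges(c("A B", "B C")))
  expect_equal(nClusters(cs), 1)
  expect_setequal(clusterMembers(cs)[[1]], c("A", "B", "C"))
  expect_equal(clusterGE(cs), 0.0)
  expect_equal(clusterSeeds(cs), "B")    # degree-2 midpoint seeds first
})

test_that("clustering is deterministic, member for member", {
  g <- makePlantedPartition(c(8, 8, 8), 0.85, 0.05, seed = 9)$graph
  for (mode in c("unweighted", "ge-wr")) {
    a <- runGE(g, mode = mode)
    b <- runGE(g, mode = mode)
    expect_identical(clusterMembers(a), clusterMembers(b))
    expect_identical(clusterSeeds(a), clusterSeeds(b))
    expect_identical(clusterGE(a), clusterGE(b))
  }
})

test_that("no single neighbor addition can improve an emitted cluster", {
  for (s in 1:6) {
    g <- makeERRandom(sample(10:20, 1), sample(20:40, 1), seed = s + 20)
    cs <- runGE(g)
    for (i in seq_len(nClusters(cs))) {
      mem <- clusterMembers(cs)[[i]]
      st <- clusterEntropy(g, mem)
      nbs <- setdiff(
        unique(unlist(lapply(mem, function(v)
          names(igraph::neighbors(g, v))))), mem)
      for (v in nbs)
        expect_gte(deltaEntropyMove(st, v, "add"), -1e-12)
    }
  }
})

test_that("shared-node clique chains yield overlapping clusters", {
  pp <- makePlantedPartition(c(5, 5, 5), 1, 0, overlapNodes = 1, seed = 1)
  cs <- runGE(pp$graph)
  ov <- overlapStatistics(cs)
  expect_gte(length(ov$nodes), 1)
  expect_gte(ov$nOverlappingClusters, 2)
  # every cluster member belongs to >= 1 cluster; overlap nodes to >= 2
  counts <- table(unlist(clusterMembers(cs)))
  expect_true(all(counts[ov$nodes] >= 2))
})

test_that("every iteration covers the emitted members, singletons included", {
  g <- makeERRandom(40, 60, seed = 4)
  cs <- runGE(g)
  expect_true(all(unlist(clusterMembers(cs)) %in% coveredNodes(cs)))
  expect_equal(sort(coveredNodes(cs)), sort(igraph::V(g)$name))
})

test_that("cluster TSV and GMT writers round-trip and stay stable", {
  cu <- makeCliqueUnion(c(4, 3))
  cs <- runGE(cu$graph)
  tf <- withr::local_tempfile()
  writeClustersTSV(cs, tf)
  cs2 <- readClustersTSV(tf)
  expect_identical(clusterMembers(cs2), clusterMembers(cs))
  expect_identical(clusterSeeds(cs2), clusterSeeds(cs))
  expect_equal(entropyMode(cs2), entropyMode(cs))

  tg <- withr::local_tempfile()
  writeClustersGMT(cs, tg)
  sets <- readGMT(tg)
  expect_identical(unname(sets), clusterMembers(cs))
})
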