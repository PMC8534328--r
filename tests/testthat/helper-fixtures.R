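# Fixtures and independent oracles, all built in code at test time.

# Graph from "A B" / "A B 0.5" strings via the package reader.
g_from_edges <- function(lines, hasWeights = FALSE) {
  tf <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, tf)
  readEdgeList(tf, hasWeights = hasWeights)
}

clique_edges <- function(members) {
  m <- t(combn(members, 2))
  paste(m[, 1], m[, 2])
}

# Two K5s joined through one shared node S.
shared_k5_pair <- function() {
  a <- c(paste0("A", 1:4), "S")
  b <- c(paste0("B", 1:4), "S")
  list(graph = g_from_edges(c(clique_edges(a), clique_edges(b))),
       blocks = list(K5A = sort(a), K5B = sort(b)), shared = "S")
}

# Independent full-recomputation oracle for seed-cluster graph entropy:
# plain double loop over nodes and incident edges, straight from the
# formulas, sharing no code with the incremental implementation.
oracle_cluster_entropy <- function(g, cluster, mode) {
  cluster <- toupper(cluster)
  ends <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(ends))
  total <- 0
  for (v in igraph::V(g)$name) {
    hit <- ends[, 1] == v | ends[, 2] == v
    if (!any(hit)) next
    other <- ifelse(ends[hit, 1] == v, ends[hit, 2], ends[hit, 1])
    inside <- other %in% cluster
    m <- sum(inside); k <- sum(!inside)
    Wi <- sum(w[hit][inside]); Wo <- sum(w[hit][!inside])
    pi <- m / (m + k); po <- k / (m + k)
    plog <- function(p) if (p > 0) p * log2(p) else 0
    total <- total + switch(mode,
      "unweighted" = -plog(pi) - plog(po),
      "ge-mw" = -Wi * plog(pi) - Wo * plog(po),
      "ge-wr" = {
        Wt <- Wi + Wo
        if (Wt > 0) -plog(Wi / Wt) - plog(Wo / Wt) else 0
      })
  }
  total
}

# Exhaustive double-loop evaluation oracle over all cluster x reference
# pairs (set arithmetic only).
oracle_avg_scores <- function(clusters, refs) {
  bestF <- bestP <- numeric(length(clusters))
  for (i in seq_along(clusters)) {
    fmax <- pmax_p <- 0
    for (r in refs) {
      ov <- length(intersect(clusters[[i]], r))
      p <- ov / length(clusters[[i]])
      rec <- ov / length(r)
      f <- if (p + rec > 0) 2 * p * rec / (p + rec) else 0
      fmax <- max(fmax, f)
      pmax_p <- max(pmax_p, p)
    }
    bestF[i] <- fmax
    bestP[i] <- pmax_p
  }
  list(meanF = mean(bestF), meanP = mean(bestP))
}

random_cluster_instance <- function(seed) {
  set.seed(seed)
  pool <- paste0("P", 1:30)
  cl <- replicate(sample(2:6, 1),
                  sample(pool, sample(2:8, 1)), simplify = FALSE)
  names(cl) <- paste0("c", seq_along(cl))
  rf <- replicate(sample(2:6, 1),
                  sample(pool, sample(2:8, 1)), simplify = FALSE)
  names(rf) <- paste0("r", seq_along(rf))
  list(clusters = cl, refs = rf)
}
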