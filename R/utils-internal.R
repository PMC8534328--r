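# Internal numerics and graph indexing shared by the entropy and clustering
# code. All entropies are in bits (log base 2); 0*log(0) is taken as 0.

# Strict-decrease tolerance: a move "decreases GE" iff delta < -.GE_TOL.
# Shared by the prune and growth phases to prevent oscillation on ties.
.GE_TOL <- 1e-12

.MODES <- c("unweighted", "ge-mw", "ge-wr")

.norm_mode <- function(mode) {
  m <- gsub("_", "-", tolower(as.character(mode)[1]), fixed = TRUE)
  if (!m %in% .MODES)
    stop("unknown entropy mode '", mode, "'; expected one of ",
         paste(.MODES, collapse = ", "), call. = FALSE)
  m
}

# Binary entropy in bits, vectorized, with the 0 log 0 := 0 convention.
# Arguments are clamped to [0, 1]: incremental weight sums can overshoot
# the total by one ulp and a negative 1-p would poison log2.
.h2 <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  q <- 1 - p
  t1 <- t2 <- numeric(length(p))
  i1 <- p > 0
  t1[i1] <- -p[i1] * log2(p[i1])
  i2 <- q > 0
  t2[i2] <- -q[i2] * log2(q[i2])
  t1 + t2
}

# Node entropy for the binary seed-cluster split, vectorized over nodes.
# m:  number of edges of v into the cluster, deg: degree of v,
# Wi: weight sum of edges into the cluster, Wt: total incident weight.
#   unweighted: H2(m/deg)
#   ge-wr:      H2(Wi/(Wi+Wo))  (weight-sum ratios replace edge-count ratios)
#   ge-mw:      -Wi*p_i*log2(p_i) - Wo*p_o*log2(p_o)  with p from edge counts
# Degree-0 nodes have entropy 0 in every mode; a side with zero total weight
# contributes 0 in ge-wr.
.node_entropy_vec <- function(m, deg, Wi, Wt, mode) {
  out <- numeric(length(m))
  pos <- deg > 0
  if (!any(pos)) return(out)
  m <- m[pos]; deg <- deg[pos]; Wi <- Wi[pos]; Wt <- Wt[pos]
  e <- switch(mode,
    "unweighted" = .h2(m / deg),
    "ge-wr" = {
      r <- numeric(length(Wi))
      wpos <- Wt > 0
      r[wpos] <- Wi[wpos] / Wt[wpos]
      .h2(r) * as.numeric(wpos)   # zero total weight contributes 0
    },
    "ge-mw" = {
      p <- m / deg
      po <- 1 - p
      Wo <- pmax(Wt - Wi, 0)   # guard one-ulp overshoot of Wi
      ifelse(p > 0, -Wi * p * log2(p), 0) +
        ifelse(po > 0, -Wo * po * log2(po), 0)
    },
    stop("unknown mode"))
  out[pos] <- e
  out
}

# Flat adjacency index over an igraph object: integer neighbor lists with
# aligned edge weights, degrees, and total incident weights. Node order is
# the igraph vertex order; all ordering decisions downstream re-sort by
# (degree desc, name asc) so vertex order never matters for results.
.graph_index <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1.0, nrow(el))
  f <- factor(c(el[, 1], el[, 2]), levels = seq_len(n))
  adj <- split(as.integer(c(el[, 2], el[, 1])), f)
  wl <- split(c(w, w), f)
  deg <- lengths(adj)
  list(n = n, names = nm, adj = adj, w = wl, deg = deg,
       wtot = vapply(wl, sum, numeric(1), USE.NAMES = FALSE))
}

# Mutable seed-cluster state for incremental GE updates: membership flags,
# per-node inside-edge counts m, inside-weight sums Wi, per-node entropies
# and their running total. Environments give in-place updates in the hot loop.
.state_init <- function(idx, members, mode) {
  st <- new.env(parent = emptyenv())
  st$inC <- logical(idx$n)
  st$inC[members] <- TRUE
  st$m <- integer(idx$n)
  st$Wi <- numeric(idx$n)
  for (v in members) {
    nb <- idx$adj[[v]]
    if (length(nb)) {
      st$m[nb] <- st$m[nb] + 1L
      st$Wi[nb] <- st$Wi[nb] + idx$w[[v]]
    }
  }
  st$e <- .node_entropy_vec(st$m, idx$deg, st$Wi, idx$wtot, mode)
  st$total <- sum(st$e)
  st
}

# GE change if node v were added to (add = TRUE) or removed from the cluster.
# Only v's neighbors change entropy: e(v) itself depends on the membership of
# v's neighbors, not of v. O(deg(v)); the state is not modified.
.delta_move <- function(idx, st, v, add, mode) {
  nb <- idx$adj[[v]]
  if (!length(nb)) return(0)
  sgn <- if (add) 1L else -1L
  m_new <- st$m[nb] + sgn
  Wi_new <- st$Wi[nb] + sgn * idx$w[[v]]
  e_new <- .node_entropy_vec(m_new, idx$deg[nb], Wi_new, idx$wtot[nb], mode)
  sum(e_new) - sum(st$e[nb])
}

.apply_move <- function(idx, st, v, add, mode) {
  nb <- idx$adj[[v]]
  if (length(nb)) {
    sgn <- if (add) 1L else -1L
    st$m[nb] <- st$m[nb] + sgn
    st$Wi[nb] <- st$Wi[nb] + sgn * idx$w[[v]]
    e_new <- .node_entropy_vec(st$m[nb], idx$deg[nb], st$Wi[nb],
                               idx$wtot[nb], mode)
    st$total <- st$total + sum(e_new) - sum(st$e[nb])
    st$e[nb] <- e_new
  }
  st$inC[v] <- add
  invisible(st)
}

# Deterministic visiting order: degree descending, then node name ascending
# in the C locale (radix) so results do not depend on the session locale.
.order_by_degree <- function(idx, nodes) {
  nodes[order(-idx$deg[nodes], idx$names[nodes], method = "radix")]
}
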