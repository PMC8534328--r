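---
title: "Detecting overlapping functional modules by graph-entropy minimization"
author: "GEclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting overlapping functional modules by graph-entropy minimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GEclust)
```

## The problem

Proteins act in concert: complexes and pathways appear in a
protein–protein interaction (PPI) network as densely connected groups of
nodes. Because one protein participates in several complexes and
processes, the modules we want to recover *overlap* — a constraint that
rules out partition-based community detection, which assigns each node to
exactly one cluster. GEclust predicts overlapping functional modules by a
local seed-growth search driven by a single objective, graph entropy.

## Graph entropy

Let an undirected graph $G$ be divided into $k$ subgraphs
$C_1,\dots,C_k$. For a node $v$ with degree $d$, let $p(x_i)$ be the
fraction of $v$'s edges whose other endpoint lies in $C_i$. The node
entropy is

$$e(v) = -\sum_{i=1}^{k} p(x_i)\,\log_2 p(x_i),$$

and the graph entropy (GE) is $e(G) = \sum_{v \in V} e(v)$. A node whose
edges all stay in one subgraph contributes nothing; a node whose edges are
split evenly contributes the most. Low GE therefore means high modularity.

The clustering only ever uses the binary split into a *seed cluster* $C$
and the rest, where the node entropy reduces to
$e(v) = -p(x_i)\log_2 p(x_i) - p(x_o)\log_2 p(x_o)$ with $p(x_i)$
($p(x_o)$) the fraction of $v$'s edges ending inside (outside) $C$.
Note that $e(v)$ depends on where $v$'s *neighbors* sit, not on $v$'s own
membership — this is what makes O(degree) incremental updates possible
(`deltaEntropyMove()`).

For weighted networks two variants replace the unweighted node entropy.
With $W_i$ ($W_o$) the sum of $v$'s edge weights into (out of) the
cluster:

* **GE-MW** (multiplied weights):
  $e(v) = -W_i\,p(x_i)\log_2 p(x_i) - W_o\,p(x_o)\log_2 p(x_o)$. The two
  entropy terms are scaled by the weight mass on each side; values are not
  bounded by 1 bit and the objective is not normalized across nodes, so we
  treat this mode as experimental.
* **GE-WR** (weighted ratios):
  $e(v) = H_2\!\left(W_i/(W_i+W_o)\right)$, the binary entropy of the
  weight-sum ratio. When all weights are equal — any constant, since only
  ratios enter — GE-WR reproduces the unweighted entropy exactly, which
  the test suite asserts node-for-node. GE-WR is the variant we recommend
  for weighted networks.

## The seed-growth procedure

`runGE()` repeats six steps until every node is covered:

1. among nodes not yet in any emitted cluster, pick the one of highest
   degree as seed (ties by node name);
2. initialize the cluster as the seed's closed neighborhood;
3. **prune**: visit the seed's neighbors once, highest degree first, and
   remove each iff GE strictly decreases;
4. **grow**: sweep the cluster's outside neighbors, highest degree first,
   adding each iff GE strictly decreases; re-collect and repeat until a
   full sweep adds nothing (nodes pruned in step 3 may return);
5. emit the cluster at the GE minimum the search reached;
6. mark all emitted members covered and continue.

Every emitted member is marked covered — including singletons, which
guarantees termination in at most $|V|$ iterations — but clusters below
`minClusterSize` (default 2) are excluded from the output. Because each
cluster is grown independently and coverage only constrains *seeding*,
clusters from different seeds can share members: that is where the
overlap comes from.

Two readings of step 5 are possible; since steps 3–4 only ever accept
strictly decreasing moves, the final state *is* the running minimum, so
"emit at the lowest GE" and "emit the final state" coincide and no
discard branch is reachable. Similarly, whether step 4 re-collects
neighbors after each addition or per sweep is immaterial at the fixpoint;
we re-collect per sweep.

## Edge weighting

Three weighting schemes feed the weighted modes:

* **none** — every edge weighs 1; with `mode = "unweighted"` the weights
  are ignored entirely.
* **probabilistic** — STRING-style confidence scores (integers 0–999,
  kept as the `score` edge attribute by `readStringLinks()`) divided by
  1000, following the STRING convention of reading the combined score as
  a probability.
* **topological** — the Jaccard index of the endpoints' neighborhoods,
  $|N(u)\cap N(v)| / |N(u)\cup N(v)|$, with $u$ and $v$ excluded from
  both sets (a pure common-neighbor ratio; the endpoints themselves would
  otherwise inflate every union). An edge between nodes with no other
  neighbors gets weight 0.

Input canonicalization upper-cases node identifiers, drops self-loops and
collapses duplicate undirected edges keeping the **maximum** weight — the
strongest available evidence for the interaction. The STRING score
threshold (default 700, inclusive) keeps only high-confidence physical
links. Degree, used for seeding and visiting order, is always the
unweighted edge count: weights influence the entropy only.

## Evaluation

Against a reference collection (protein complexes, GO annotation groups,
or planted blocks), each cluster $C_i$ is scored against each module
$r_j$ by precision $P_{ij}=|C_i\cap r_j|/|C_i|$, recall
$R_{ij}=|C_i\cap r_j|/|r_j|$ and their harmonic mean $F_{ij}$; the
cluster keeps its best match and `evaluateClusters()` averages the best
scores. Before scoring, reference members absent from the network are
removed from the references, then cluster members absent from the
filtered reference universe are removed from the clusters; modules or
clusters emptied by filtering are dropped (averaging over them would be
undefined). Ties between equally scoring references break by reference
name so reports are deterministic.

Three further statistics:

* **homogeneity** — the percentage of clusters with best precision at or
  above 0.6 (inclusive), i.e. clusters drawn mostly from one module;
* **overlap** — nodes appearing in ≥ 2 clusters and clusters containing
  at least one such node, computed on the raw cluster set *before*
  reference filtering, which is how the overlap definitions are stated;
* **novel members** — matching clusters against *unfiltered* references
  (so a cluster may complete a module with proteins the network knows but
  the annotation lacks), clusters with best F strictly above 0.9 report
  their members missing from the matched module as candidates for
  annotation.

The two thresholds deliberately differ in strictness: homogeneity is
inclusive at 0.6, the novel-member cutoff exclusive at 0.9.

## Synthetic benchmarks

`makeCliqueUnion()` (disjoint cliques; exact-recovery fixture),
`makePlantedPartition()` (within-block probability `pIn`, cross-block
`pOut`, optional members shared by consecutive blocks) and
`makeERRandom()` (uniform simple graph with exactly `n` nodes and `m`
edges) generate canonical networks plus, where blocks exist, the planted
`ReferenceSet`. One seeded RNG drives each call and the seed is recorded
on the graph, so a fixed seed reproduces the edge list byte for byte.
With `pIn = 1`, `pOut = 0` and no overlap the planted partition reduces
exactly to the clique union, which anchors the generator tests. The ER
generator samples `m` distinct node pairs without replacement, matching
"same number of nodes and edges" null comparisons; we use the fixed-m
sampler only, as degree-preserving rewiring adds nothing for this null.

Verification problem sizes, chosen as comfortable desk-scale instances:
clique recovery on K5 + K6 + K4; planted-partition recovery on 10 blocks
of 20 nodes at `pIn = 0.9`, `pOut = 0.01` (average best F ≥ 0.9 across
seeds); the random-network null on 2000 nodes and 8000 edges, where
essentially all nodes remain singletons; entropy-oracle checks on a few
hundred random graphs of at most 12 nodes.

What these fixtures do *not* emulate about real PPI data: scale-free
degree distributions, the heavy overlap structure of real complexes,
score-dependent noise in confidence values, and identifier ambiguity
(Ensembl vs gene symbols). Passing the synthetic suite shows the
machinery is correct, not that any particular biological network will
yield biologically meaningful modules.

## Numerical choices and degenerate inputs

* Entropies are in bits (log base 2). The base is a global rescaling and
  cannot change any accept/reject decision; bits make the worked examples
  round numbers.
* $0\log 0 := 0$ throughout; probabilities are clamped to $[0,1]$ before
  the logarithm because incremental weight sums can overshoot the cached
  total by one ulp.
* A move "decreases GE" iff its delta is below $-10^{-12}$. The strict
  tolerance prevents oscillation on exact ties, and ties are otherwise
  resolved by visiting order (degree descending, then node name in the C
  locale), making every run reproducible across platforms and locales.
* Isolated nodes have entropy 0 in every mode; in GE-WR a node whose
  incident weights sum to 0 contributes 0; in GE-MW a side with zero
  weight contributes 0 through its multiplier.
* Empty graphs cluster to an empty result; an empty seed cluster is a
  validation error; all-singleton outputs are valid (and expected on
  random graphs).

## Known limitations

* **Whole-neighborhood collapse.** If a seed is adjacent to its entire
  connected component — as the shared node of two vertex-joined cliques
  always is, having the strictly highest degree — the initial cluster is
  the whole component, whose binary-split GE is 0, the global minimum. No
  strictly decreasing move exists and the component is emitted as one
  cluster. Overlap therefore cannot arise from two cliques sharing a
  single dominant node; it does arise as soon as no single node dominates
  the component, e.g. in a chain of three cliques sharing nodes between
  consecutive pairs, which is the fixture we use to demonstrate it.
* **Remove-optimality is not guaranteed.** The prune pass visits each
  seed neighbor exactly once before growth; after growth, a removal may
  again be profitable. The emitted cluster is guaranteed locally optimal
  against single *additions* (the growth fixpoint), not against single
  removals. Iterating prune/growth to a joint fixpoint would change the
  procedure and its published behavior, so we do not.
* GE-MW is non-normalized (weights multiply, not renormalize) and in our
  experience behaves erratically on heterogeneous weights; it is provided
  for completeness and flagged experimental.
* The package does not map identifiers, traverse the GO DAG, or download
  networks; references and networks must share a namespace (upper-cased
  gene symbols by convention).

## Session info

```{r}
sessionInfo()
```
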