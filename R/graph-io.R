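# Reading, canonicalizing and weighting undirected PPI networks.
#
# Canonical form: node names upper-cased, no self-loops, each undirected
# edge stored once (duplicates collapse to the maximum weight/score -- the
# strongest evidence), every weight finite and >= 0, weight 1.0 when the
# input is unweighted.

.read_lines_nocomment <- function(path) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

# Collapse parallel edges / self-loops into a canonical simple graph.
# Duplicate undirected edges keep the maximum weight (and score, if given).
.make_canonical_graph <- function(from, to, weight = NULL, score = NULL) {
  from <- toupper(from)
  to <- toupper(to)
  all_nodes <- sort(unique(c(from, to)))
  keep <- from != to
  from2 <- from[keep]; to2 <- to[keep]
  a <- pmin(from2, to2)
  b <- pmax(from2, to2)
  w <- if (is.null(weight)) rep(1.0, length(a)) else weight[keep]
  s <- if (is.null(score)) NULL else score[keep]
  key <- paste(a, b, sep = "\r")
  o <- order(key, method = "radix")
  a <- a[o]; b <- b[o]; w <- w[o]; key <- key[o]
  if (!is.null(s)) s <- s[o]
  grp <- match(key, unique(key))
  wmax <- vapply(split(w, grp), max, numeric(1), USE.NAMES = FALSE)
  first <- !duplicated(grp)
  d <- data.frame(from = a[first], to = b[first], weight = wmax,
                  stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(d, directed = FALSE,
                                     vertices = all_nodes)
  if (!is.null(s)) {
    smax <- vapply(split(s, grp), max, numeric(1), USE.NAMES = FALSE)
    g <- igraph::set_edge_attr(g, "score", value = as.integer(smax))
  }
  g
}

#' Read an undirected network from a plain edge list
#'
#' Parses a 2- or 3-column delimited edge list into a canonical undirected
#' `igraph` graph: node names are upper-cased, self-loops dropped, and
#' duplicate undirected edges collapsed keeping the maximum weight. Lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path path to the edge-list file.
#' @param hasWeights if `TRUE`, a third numeric column gives edge weights;
#'   otherwise every edge gets weight 1.0.
#' @param delimiter field separator; `NULL` (default) splits on runs of
#'   spaces/tabs.
#' @return an `igraph` object with a `weight` edge attribute.
#' @seealso [writeEdgeList()], [readStringLinks()]
#' @examples
#' tf <- tempfile()
#' writeLines(c("a b", "b c", "c d"), tf)
#' g <- readEdgeList(tf)
#' igraph::vcount(g)  # 4
#' @export
readEdgeList <- function(path, hasWeights = FALSE, delimiter = NULL) {
  lc <- .read_lines_nocomment(path)
  nfields <- if (hasWeights) 3L else 2L
  split_re <- if (is.null(delimiter)) "[ \t]+" else delimiter
  fixed <- !is.null(delimiter)
  parts <- strsplit(trimws(lc$lines), split_re, fixed = fixed)
  bad <- which(lengths(parts) != nfields)
  if (length(bad))
    stop("parse error at line ", lc$lineno[bad[1]], ": expected ",
         nfields, " fields, got ", length(parts[[bad[1]]]), call. = FALSE)
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  weight <- NULL
  if (hasWeights) {
    wtxt <- vapply(parts, `[[`, character(1), 3L)
    weight <- suppressWarnings(as.numeric(wtxt))
    badw <- which(!is.finite(weight))
    if (length(badw))
      stop("parse error at line ", lc$lineno[badw[1]],
           ": non-numeric weight '", wtxt[badw[1]], "'", call. = FALSE)
    neg <- which(weight < 0)
    if (length(neg))
      stop("validation error at line ", lc$lineno[neg[1]],
           ": negative weight", call. = FALSE)
  }
  if (length(from) == 0)
    return(igraph::make_empty_graph(0, directed = FALSE))
  .make_canonical_graph(from, to, weight)
}

#' Read a STRING physical-links file
#'
#' Parses the STRING dialect (header plus `protein1 protein2 combined_score`
#' columns, scores 0-999) and keeps only interactions whose confidence score
#' meets the threshold (inclusive; 700 is the conventional high-confidence
#' cutoff). The raw integer score is retained as edge attribute `score` so
#' that [applyProbabilisticWeights()] can later turn it into a probability;
#' the `weight` attribute starts at 1.0.
#'
#' @param path path to the links file.
#' @param scoreThreshold minimum combined score to keep an edge
#'   (default 700).
#' @return a canonical `igraph` object with `weight` and `score` edge
#'   attributes.
#' @export
readStringLinks <- function(path, scoreThreshold = 700) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1)
    stop("format error: empty STRING links file", call. = FALSE)
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  need <- c("protein1", "protein2", "combined_score")
  pos <- match(need, header)
  if (anyNA(pos))
    stop("format error: missing column(s) ",
         paste(need[is.na(pos)], collapse = ", "), call. = FALSE)
  body <- lines[-1]
  keep <- !grepl("^\\s*#", body)
  body <- body[keep]
  if (!length(body))
    return(igraph::make_empty_graph(0, directed = FALSE))
  parts <- strsplit(trimws(body), "[ \t]+")
  short <- which(lengths(parts) < max(pos))
  if (length(short))
    stop("parse error at line ", short[1] + 1L, ": too few fields",
         call. = FALSE)
  p1 <- vapply(parts, `[[`, character(1), pos[1])
  p2 <- vapply(parts, `[[`, character(1), pos[2])
  stxt <- vapply(parts, `[[`, character(1), pos[3])
  badint <- which(!grepl("^[0-9]+$", stxt))
  if (length(badint))
    stop("parse error at line ", badint[1] + 1L,
         ": non-integer combined_score '", stxt[badint[1]], "'",
         call. = FALSE)
  score <- as.integer(stxt)
  sel <- score >= scoreThreshold
  if (!any(sel))
    return(igraph::make_empty_graph(0, directed = FALSE))
  .make_canonical_graph(p1[sel], p2[sel], score = score[sel])
}

#' Use STRING confidence scores as probabilistic edge weights
#'
#' Sets each edge weight to `score / 1000`, mapping the integer STRING
#' combined score (0-999) onto (0, 1] as the probability that the
#' interaction is real. Requires the `score` attribute retained by
#' [readStringLinks()].
#'
#' @param graph a canonical `igraph` with a `score` edge attribute.
#' @return the graph with updated `weight`.
#' @export
applyProbabilisticWeights <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  s <- igraph::E(graph)$score
  if (igraph::ecount(graph) > 0 && is.null(s))
    stop("validation error: edges lack a 'score' attribute; ",
         "read the network with readStringLinks()", call. = FALSE)
  if (igraph::ecount(graph) > 0)
    graph <- igraph::set_edge_attr(graph, "weight", value = s / 1000)
  graph
}

#' Weight edges by the Jaccard index of endpoint neighborhoods
#'
#' For each edge \{u, v\} the weight becomes
#' `|N(u) ∩ N(v)| / |N(u) ∪ N(v)|` where the neighbor sets exclude u and v
#' themselves, i.e. a pure common-neighbor ratio. Edges whose endpoints
#' have no other neighbors get weight 0.
#'
#' @param graph a canonical `igraph`.
#' @return the graph with topological (Jaccard) `weight`s in \[0, 1\].
#' @export
applyTopologicalWeights <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::ecount(graph) == 0) return(graph)
  adj <- igraph::as_adj_list(graph)
  adj <- lapply(adj, as.integer)
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- vapply(seq_len(nrow(el)), function(i) {
    u <- el[i, 1]; v <- el[i, 2]
    nu <- setdiff(adj[[u]], c(u, v))
    nv <- setdiff(adj[[v]], c(u, v))
    un <- length(union(nu, nv))
    if (un == 0) 0 else length(intersect(nu, nv)) / un
  }, numeric(1))
  igraph::set_edge_attr(graph, "weight", value = w)
}

#' Write a canonical three-column edge list
#'
#' Emits `node1 TAB node2 TAB weight` with `node1 < node2` and rows sorted
#' lexicographically, so equal graphs always produce byte-identical files.
#' Weights are printed with full precision and survive a read/write/read
#' round trip exactly.
#'
#' @param graph a canonical `igraph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::ecount(graph) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph, names = TRUE)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1.0, nrow(el))
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  o <- order(a, b, method = "radix")
  writeLines(sprintf("%s\t%s\t%s", a[o], b[o],
                     formatC(w[o], digits = 17, format = "g")), path)
  invisible(path)
}
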