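#' Build a high-confidence PPI graph from scored edges
#'
#' Applies the STRING-style combined-score threshold (default 900,
#' i.e. "highest confidence" 0.9) and returns a simple undirected
#' graph: no self-loops, no parallel edges, symmetric adjacency.
#' Nodes left without any retained edge are dropped unless listed in
#' `keep_nodes` (e.g. a whitelist of miRNA targets), in which case they
#' stay as isolated vertices.
#'
#' @param edges Tibble of scored edges (`protein_a`, `protein_b`,
#'   `combined_score` on the 0-1000 integer scale).
#' @param min_score Minimum combined score (inclusive).
#' @param keep_nodes Optional character vector of node labels to retain
#'   even when isolated.
#' @return A `ppi_graph`: list with `nodes` (sorted labels) and `adj`
#'   (named list of sorted neighbor vectors).
#' @export
build_graph <- function(edges, min_score = 900, keep_nodes = NULL) {
  cx_assert(all(edges$combined_score >= 0 & edges$combined_score <= 1000),
            "combined_score must lie in [0, 1000]")
  keep <- edges$combined_score >= min_score & edges$protein_a != edges$protein_b
  ed <- unique(edges[keep, c("protein_a", "protein_b")])
  nodes <- sort(unique(c(ed$protein_a, ed$protein_b, keep_nodes)))
  if (length(nodes) == 0) warn("build_graph: empty graph")
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  for (i in seq_len(nrow(ed))) {
    a <- ed$protein_a[i]; b <- ed$protein_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, function(x) sort(unique(x)))
  structure(list(nodes = nodes, adj = adj), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  n_edges <- sum(lengths(x$adj)) / 2
  cat(sprintf("<ppi_graph> %d node(s), %d edge(s)\n", length(x$nodes), n_edges))
  invisible(x)
}

# BFS distances (and optionally shortest-path counts / predecessor
# order) from a source; the visit order is deterministic because
# adjacency lists are sorted.
bfs_from <- function(g, s) {
  dist <- stats::setNames(rep(NA_integer_, length(g$nodes)), g$nodes)
  dist[s] <- 0L
  queue <- s
  order <- character(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in g$adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  list(dist = dist, order = order)
}

#' Degree centrality
#'
#' @param g A `ppi_graph`.
#' @return Named integer vector of neighbor counts.
#' @export
degree_centrality <- function(g) {
  vapply(g$adj, length, integer(1))
}

#' Closeness centrality
#'
#' The default (`mode = "harmonic"`) is the reciprocal-distance sum
#' \eqn{C(v) = \sum_{w \ne v} 1/d(v, w)} with unreachable nodes
#' contributing 0, which stays well-defined on the disconnected graphs
#' that score thresholding produces. `mode = "classic"` gives
#' \eqn{(n_c - 1)/\sum d} restricted to each node's connected component
#' (with \eqn{n_c} the component size); isolated nodes score 0 in both
#' modes. The two modes can rank nodes differently on disconnected
#' graphs, which is why the choice is explicit.
#'
#' @param g A `ppi_graph`.
#' @param mode `"harmonic"` (default) or `"classic"`.
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(g, mode = c("harmonic", "classic")) {
  mode <- match.arg(mode)
  out <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  for (v in g$nodes) {
    d <- bfs_from(g, v)$dist
    d <- d[names(d) != v & !is.na(d)]
    if (length(d) == 0) next
    out[v] <- if (mode == "harmonic") sum(1 / d) else length(d) / sum(d)
  }
  out
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness over unordered node pairs
#' with endpoints excluded:
#' \eqn{B(v) = \sum_{s < t, s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}},
#' computed with Brandes' dependency-accumulation algorithm. Only node
#' rankings are consumed downstream, and a normalization constant would
#' not change them.
#'
#' @param g A `ppi_graph`.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(g) {
  n <- length(g$nodes)
  bc <- stats::setNames(numeric(n), g$nodes)
  for (s in g$nodes) {
    dist <- stats::setNames(rep(NA_integer_, n), g$nodes)
    sigma <- stats::setNames(numeric(n), g$nodes)
    delta <- stats::setNames(numeric(n), g$nodes)
    preds <- stats::setNames(vector("list", n), g$nodes)
    dist[s] <- 0L; sigma[s] <- 1
    queue <- s; stack <- character(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      stack <- c(stack, v)
      for (w in g$adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    for (w in rev(stack)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2 # each unordered pair was accumulated from both endpoints
}

# Deterministic shortest-path tree rooted at s: BFS in sorted label
# order, parent = lexicographically smallest equal-distance predecessor.
# Returns the parent map over s's reachable component.
sp_tree <- function(g, s) {
  b <- bfs_from(g, s)
  reach <- names(b$dist)[!is.na(b$dist)]
  parent <- stats::setNames(rep(NA_character_, length(reach)), reach)
  for (v in setdiff(reach, s)) {
    cands <- g$adj[[v]][!is.na(b$dist[g$adj[[v]]]) &
                          b$dist[g$adj[[v]]] == b$dist[v] - 1L]
    parent[v] <- min(cands)
  }
  parent
}

# Subtree sizes of a parent-map tree (each node counts itself).
subtree_sizes <- function(parent) {
  size <- stats::setNames(rep(1L, length(parent)), names(parent))
  depth_order <- names(sort(vapply(names(parent), function(v) {
    d <- 0L
    while (!is.na(parent[v])) { v <- parent[v]; d <- d + 1L }
    d
  }, integer(1)), decreasing = TRUE))
  for (v in depth_order) {
    p <- parent[v]
    if (!is.na(p)) size[p] <- size[p] + size[v]
  }
  size
}

#' BottleNeck centrality
#'
#' The cytoHubba-style BottleNeck metric: for every root \eqn{s}, build
#' a shortest-path tree \eqn{T_s} over the root's reachable component;
#' a node \eqn{v \ne s} scores one point from that root when its
#' subtree contains strictly more than \eqn{|V(T_s)|/4} nodes. The
#' centrality is the sum of points over all roots. Shortest-path trees
#' are not unique; determinism is fixed by BFS in sorted label order
#' with the lexicographically smallest equal-distance predecessor as
#' parent.
#'
#' @param g A `ppi_graph`.
#' @param fraction Subtree-size threshold as a fraction of the tree
#'   (default 1/4).
#' @param strict Require strictly greater than the threshold (default
#'   `TRUE`).
#' @return Named integer vector.
#' @export
bottleneck_centrality <- function(g, fraction = 0.25, strict = TRUE) {
  bn <- stats::setNames(rep(0L, length(g$nodes)), g$nodes)
  for (s in g$nodes) {
    parent <- sp_tree(g, s)
    size <- subtree_sizes(parent)
    thr <- length(parent) * fraction
    scorers <- names(size)[if (strict) size > thr else size >= thr]
    scorers <- setdiff(scorers, s)
    bn[scorers] <- bn[scorers] + 1L
  }
  bn
}

#' Top-k nodes under a score vector
#'
#' Nodes sorted by score descending with a secondary sort on the node
#' label for determinism. Ties at the k-th boundary are all included,
#' so the list may exceed `k`.
#'
#' @param scores Named numeric vector.
#' @param k Number of nodes requested (`k >= 1`).
#' @return Character vector of node labels.
#' @export
top_k <- function(scores, k = 10) {
  cx_assert(k >= 1, "k must be >= 1")
  if (length(scores) == 0) return(character(0))
  ord <- order(-scores, names(scores))
  sorted <- scores[ord]
  if (length(sorted) <= k) return(names(sorted))
  cutoff <- sorted[k]
  names(sorted)[sorted >= cutoff]
}

#' Hub genes as the intersection of four top-k centrality lists
#'
#' Ranks every node by degree, closeness, betweenness and BottleNeck
#' centrality and returns the intersection of the four top-`k` lists as
#' the hub set, together with the per-metric rankings for reporting.
#'
#' @param g A `ppi_graph`.
#' @param k Size of each per-metric list (default 10; boundary ties are
#'   included). Graphs with fewer than `k` nodes use all nodes per
#'   metric, with a warning.
#' @param closeness_mode Passed to [closeness_centrality()].
#' @return A list: `hubs` (sorted labels), `top` (named list of the
#'   four ranked lists), `scores` (tibble of all four centralities per
#'   node), `k`.
#' @export
hub_intersection <- function(g, k = 10, closeness_mode = "harmonic") {
  if (length(g$nodes) < k) {
    warn(sprintf("hub_intersection: graph has %d node(s) < k = %d; using all nodes",
                 length(g$nodes), k))
  }
  scores <- list(
    degree = degree_centrality(g),
    closeness = closeness_centrality(g, mode = closeness_mode),
    betweenness = betweenness_centrality(g),
    bottleneck = bottleneck_centrality(g)
  )
  top <- lapply(scores, top_k, k = k)
  hubs <- sort(Reduce(intersect, top))
  score_tbl <- tibble(
    node = g$nodes,
    degree = as.integer(scores$degree[g$nodes]),
    closeness = unname(scores$closeness[g$nodes]),
    betweenness = unname(scores$betweenness[g$nodes]),
    bottleneck = as.integer(scores$bottleneck[g$nodes])
  )
  list(hubs = hubs, top = top, scores = score_tbl, k = k)
}
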