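# Independent brute-force oracles. These deliberately use a different
# machinery from the implementation: adjacency matrices and
# Floyd-Warshall distances instead of adjacency lists and BFS, explicit
# shortest-path enumeration instead of Brandes accumulation, and
# ancestor-walking instead of recursive subtree sizing.

random_graph_edges <- function(n, p) {
  labels <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(labels, 2)
  pick <- stats::runif(ncol(pairs)) < p
  tibble::tibble(
    protein_a = pairs[1, pick],
    protein_b = pairs[2, pick],
    combined_score = 1000L
  )
}

adj_matrix <- function(g) {
  n <- length(g$nodes)
  m <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
  for (v in g$nodes) m[v, g$adj[[v]]] <- 1L
  m
}

# all-pairs distances by Floyd-Warshall
oracle_dists <- function(g) {
  m <- adj_matrix(g)
  n <- nrow(m)
  d <- matrix(Inf, n, n, dimnames = dimnames(m))
  diag(d) <- 0
  d[m == 1L] <- 1
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

oracle_degree <- function(g) {
  rowSums(adj_matrix(g))
}

oracle_closeness <- function(g) {
  d <- oracle_dists(g)
  sapply(g$nodes, function(v) {
    dv <- d[v, setdiff(g$nodes, v)]
    sum(1 / dv[is.finite(dv)])
  })
}

# enumerate every shortest s-t path by backtracking on the distance
# matrix, then count how often each interior node appears
oracle_betweenness <- function(g) {
  d <- oracle_dists(g)
  m <- adj_matrix(g)
  bc <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  paths_to <- function(s, t) {
    if (s == t) return(list(s))
    preds <- g$nodes[m[, t] == 1L & d[s, ] == d[s, t] - 1]
    unlist(lapply(preds, function(u) {
      lapply(paths_to(s, u), function(p) c(p, t))
    }), recursive = FALSE)
  }
  nodes <- g$nodes
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j || !is.finite(d[nodes[i], nodes[j]])) next
      paths <- paths_to(nodes[i], nodes[j])
      for (p in paths) {
        interior <- setdiff(p, c(nodes[i], nodes[j]))
        bc[interior] <- bc[interior] + 1 / length(paths)
      }
    }
  }
  bc
}

# shortest-path tree per root (smallest-label parent rule), subtree
# sizes by walking every node's ancestor chain
oracle_bottleneck <- function(g, fraction = 0.25) {
  d <- oracle_dists(g)
  m <- adj_matrix(g)
  bn <- stats::setNames(rep(0L, length(g$nodes)), g$nodes)
  for (s in g$nodes) {
    reach <- g$nodes[is.finite(d[s, ])]
    parent <- stats::setNames(rep(NA_character_, length(reach)), reach)
    for (v in setdiff(reach, s)) {
      parent[v] <- min(g$nodes[m[, v] == 1L & d[s, ] == d[s, v] - 1])
    }
    size <- stats::setNames(rep(0L, length(reach)), reach)
    for (v in reach) {
      size[v] <- size[v] + 1L # itself
      a <- parent[v]
      while (!is.na(a)) {
        size[a] <- size[a] + 1L
        a <- parent[a]
      }
    }
    hits <- setdiff(names(size)[size > length(reach) * fraction], s)
    bn[hits] <- bn[hits] + 1L
  }
  bn
}

# strict-majority oracle over a vote vector
oracle_majority <- function(votes) {
  n <- length(votes)
  if (sum(votes == "up") > n / 2) "up"
  else if (sum(votes == "down") > n / 2) "down"
  else "ambiguous"
}

# upper-tail hypergeometric by complete enumeration of all C(N, n)
# draws from an explicit urn
oracle_hypergeom <- function(k, K, n, N) {
  urn <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(idx) sum(urn[idx]))
  mean(hits >= k)
}

# brute-force triple loop applying the triad predicates directly
oracle_triads <- function(anchors, mir_catalog, lnc_catalog, calls,
                          cwcs_cutoff = -0.4) {
  calls <- calls[calls$direction %in% c("up", "down"), ]
  dof <- function(id, cls) {
    hit <- calls$direction[calls$molecule_id == id & calls$molecule_class == cls]
    if (length(hit) == 1) hit else NA_character_
  }
  count <- 0L
  for (a in anchors) {
    ad <- dof(a, "mRNA")
    for (i in seq_len(nrow(mir_catalog))) {
      e <- mir_catalog[i, ]
      if (e$target_symbol != a) next
      if (!(e$confidence == "observed" ||
            (e$confidence == "predicted" && !is.na(e$cwcs) && e$cwcs <= cwcs_cutoff))) next
      md <- dof(e$mirna_id, "miRNA")
      if (is.na(md) || is.na(ad) || md == ad) next
      arms <- if (grepl("-(3p|5p)$", e$mirna_id)) e$mirna_id else
        paste0(e$mirna_id, c("-3p", "-5p"))
      for (j in seq_len(nrow(lnc_catalog))) {
        l <- lnc_catalog[j, ]
        if (!l$mirna_id %in% arms) next
        ld <- dof(l$lncrna_id, "lncRNA")
        if (is.na(ld) || ld != ad) next
        count <- count + 1L
      }
    }
  }
  count
}
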