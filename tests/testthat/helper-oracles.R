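# Independent oracles and small graph fixtures, kept free of the package's
# own code paths (and of igraph wherever igraph is the implementation).

# Brute-force betweenness by the pair-counting identity: for every pair
# (s, t) add sigma(s,v) * sigma(v,t) / sigma(s,t) for interior v, with BFS
# distances and path counts computed here from the adjacency matrix.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    sig <- rep(0, n); sig[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (is.infinite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
          }
          if (d[w] == d[v] + 1) sig[w] <- sig[w] + sig[v]
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
    sigma[s, ] <- sig
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(dist[s, t])) next
      for (v in seq_len(n)) {
        if (v != s && v != t && dist[s, v] + dist[v, t] == dist[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  btw
}

# Union-find connected components from an edge list over nodes 1..n.
oracle_components <- function(edges, n) {
  parent <- seq_len(n)
  find2 <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    root
  }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- find2(edges[k, 1]); b <- find2(edges[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  membership <- vapply(seq_len(n), find2, integer(1))
  match(membership, unique(membership))
}

# Hypergeometric upper tail P(X >= a) by direct summation over the support.
oracle_hyper_tail <- function(a, K, N, n) {
  ks <- max(a, max(0, n - (N - K))):min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Adjacency matrix of two K5 cliques joined by a single bridge edge (1-6).
barbell_adj <- function() {
  adj <- matrix(0, 10, 10)
  adj[1:5, 1:5] <- 1
  adj[6:10, 6:10] <- 1
  diag(adj) <- 0
  adj[1, 6] <- adj[6, 1] <- 1
  dimnames(adj) <- list(sprintf("g%02d", 1:10), sprintf("g%02d", 1:10))
  adj
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = NULL, diag = FALSE)
}

# Random connected-ish test graph as an adjacency matrix.
random_adj <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.integer(runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("g%02d", seq_len(n)), sprintf("g%02d", seq_len(n)))
  adj
}

# Partition sanity: coverage, disjointness, and no module spanning two
# components (components from the union-find oracle).
expect_valid_partition <- function(partition, adj) {
  nodes <- rownames(adj)
  expect_setequal(partition$gene_id, nodes)
  expect_false(anyDuplicated(partition$gene_id) > 0)
  comp <- oracle_components(which(upper.tri(adj) & adj > 0, arr.ind = TRUE),
                            nrow(adj))
  names(comp) <- nodes
  for (m in unique(partition$module)) {
    members <- partition$gene_id[partition$module == m]
    expect_length(unique(comp[members]), 1)
  }
}
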