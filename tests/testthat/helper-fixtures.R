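# Fixtures built in code: small graphs with hand-countable quantities.

# two triangles {a,b,c}, {d,e,f} joined by the bridge c-d; L = 7
two_triangles <- function() {
  mr_network(cbind(c("a", "b", "c", "d", "e", "f", "c"),
                   c("b", "c", "a", "e", "f", "d", "d")))
}

triangle_partition <- function() {
  as_partition(list(t1 = c("a", "b", "c"), t2 = c("d", "e", "f")))
}

# two cliques of size k joined by one bridge edge
two_cliques <- function(k) {
  pairs <- t(utils::combn(k, 2))
  e1 <- cbind(paste0("u", pairs[, 1]), paste0("u", pairs[, 2]))
  e2 <- cbind(paste0("v", pairs[, 1]), paste0("v", pairs[, 2]))
  mr_network(rbind(e1, e2, c("u1", "v1")))
}

two_cliques_partition <- function(k) {
  as_partition(list(A = paste0("u", seq_len(k)), B = paste0("v", seq_len(k))))
}

# seeded Erdos-Renyi graph with named vertices, guaranteed >= 1 edge
random_network <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::gsize(g) >= 1) break
  }
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

random_partition <- function(g, k, seed) {
  set.seed(seed)
  labs <- as.character(sample(k, igraph::vcount(g), replace = TRUE))
  stats::setNames(labs, igraph::V(g)$name)
}

# independent brute-force modularity: double loop over node pairs of the
# adjacency matrix, Q = (1/2L) sum_ij [A_ij - gamma d_i d_j / 2L] delta(c_i c_j)
brute_force_modularity <- function(g, partition, gamma = 1) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- rowSums(A)
  L <- sum(A) / 2
  p <- partition[rownames(A)]
  q <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      if (p[i] == p[j]) q <- q + A[i, j] - gamma * d[i] * d[j] / (2 * L)
    }
  }
  unname(q / (2 * L))
}

# graph with a designated member set of known intra-edge count l_target,
# padded with a disjoint path so the global edge count is exactly L_total
graph_with_module <- function(l_target, L_total) {
  # take the first l_target pairs of a clique big enough to hold them
  k <- 3
  while (choose(k, 2) < l_target) k <- k + 1
  pairs <- t(utils::combn(k, 2))[seq_len(l_target), , drop = FALSE]
  members <- paste0("m", sort(unique(as.vector(pairs))))
  e1 <- cbind(paste0("m", pairs[, 1]), paste0("m", pairs[, 2]))
  n_fill <- L_total - l_target
  stopifnot(n_fill >= 0)
  e2 <- if (n_fill > 0) {
    cbind(paste0("p", seq_len(n_fill)), paste0("p", seq_len(n_fill) + 1L))
  } else NULL
  list(network = mr_network(rbind(e1, e2)), members = members)
}
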