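# Brute-force reference implementations, independent of igraph, used to
# cross-check the topology panel on small graphs.

# adjacency matrix of an igraph, fixed node order
adj_of <- function(g) igraph::as_adjacency_matrix(g, sparse = FALSE)

# Watts-Strogatz local clustering by direct triangle counting
brute_avg_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- sum(adj[nb, nb]) / 2
    cc[i] <- 2 * links / (k * (k - 1))
  }
  mean(cc)
}

# all-pairs shortest paths by Floyd-Warshall; mean over connected pairs
brute_avg_path <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (length(v)) mean(v) else 0
}

# Newman modularity Q = sum_s (l_s/L - (d_s/2L)^2) from a membership vector
brute_modularity <- function(adj, memb) {
  L <- sum(adj) / 2
  q <- 0
  for (s in unique(memb)) {
    in_s <- memb == s
    l_s <- sum(adj[in_s, in_s]) / 2
    d_s <- sum(adj[in_s, ])
    q <- q + l_s / L - (d_s / (2 * L))^2
  }
  q
}

# within-module degree z-score and among-module connectivity, by loops
brute_zi_pi <- function(adj, memb) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  within <- vapply(seq_len(n), function(i) sum(adj[i, memb == memb[i]]),
                   numeric(1))
  zi <- numeric(n)
  for (s in unique(memb)) {
    in_s <- which(memb == s)
    if (length(in_s) >= 3) {
      mu <- mean(within[in_s]); sdv <- stats::sd(within[in_s])
      if (sdv > 0) zi[in_s] <- (within[in_s] - mu) / sdv
    }
  }
  pi_v <- vapply(seq_len(n), function(i) {
    1 - sum(vapply(unique(memb), function(s)
      (sum(adj[i, memb == s]) / deg[i])^2, numeric(1)))
  }, numeric(1))
  list(zi = zi, pi = pi_v)
}

# random connected-ish test graph with named nodes
random_test_graph <- function(n, p = 0.35, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  # ensure no isolated vertices (they are dropped at build time in the pipeline)
  deg <- igraph::degree(g)
  for (v in which(deg == 0)) {
    u <- if (v == 1) 2 else 1
    g <- igraph::add_edges(g, c(v, u))
  }
  g <- igraph::simplify(g)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

# adjusted Rand index (Hubert & Arabie) for partition recovery checks
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  exp_ <- si * sj / choose(sum(tab), 2)
  max_ <- (si + sj) / 2
  (sij - exp_) / (max_ - exp_)
}

# Wigner surmise sampler by inverse CDF: F(d) = 1 - exp(-pi d^2/4)
rwigner <- function(n) sqrt(-4 / pi * log(1 - stats::runif(n)))

# build a similarity_matrix object directly from a symmetric matrix
sim_from_matrix <- function(S, signs = NULL) {
  n <- nrow(S)
  diag(S) <- 0
  if (is.null(signs)) signs <- sign(S)
  structure(list(S = S, signs = signs,
                 otu_ids = if (is.null(rownames(S))) paste0("O", seq_len(n)) else rownames(S)),
            class = "similarity_matrix")
}
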