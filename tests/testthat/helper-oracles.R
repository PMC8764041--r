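# Brute-force graph oracles used to validate the topology metrics.
# Everything here works from a plain adjacency matrix and deliberately
# avoids igraph.

random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

graph_from_adj <- function(a) {
  dimnames(a) <- list(paste0("v", seq_len(nrow(a))),
                      paste0("v", seq_len(nrow(a))))
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# mean local clustering; k < 2 nodes contribute zero
oracle_cc <- function(a) {
  n <- nrow(a)
  local <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      tri <- tri + a[nb[i], nb[j]]
    local[v] <- tri / (k * (k - 1) / 2)
  }
  mean(local)
}

# Floyd-Warshall all-pairs shortest paths
oracle_dists <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# mean shortest-path length over connected ordered pairs
oracle_apl <- function(a) {
  d <- oracle_dists(a)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

# shortest-path counts sigma[s, t] by distance-layer recursion
oracle_path_counts <- function(a, d) {
  n <- nrow(a)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]))
    for (v in reach[order(d[s, reach])]) {
      if (v == s) next
      preds <- which(a[v, ] == 1 & d[s, ] == d[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  sigma
}

# betweenness via the pair-summation definition (not Brandes accumulation)
oracle_betweenness <- function(a) {
  d <- oracle_dists(a)
  sigma <- oracle_path_counts(a, d)
  n <- nrow(a)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t]) || sigma[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  b
}

oracle_modularity <- function(a, membership) {
  m <- sum(a) / 2
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(a[idx, idx, drop = FALSE]) / 2
    d_c <- sum(a[idx, , drop = FALSE])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# exhaustive search over all set partitions (restricted growth strings)
next_rgs <- function(rgs) {
  n <- length(rgs)
  for (i in n:2) {
    if (rgs[i] <= max(rgs[1:(i - 1)])) {
      rgs[i] <- rgs[i] + 1L
      if (i < n) rgs[(i + 1):n] <- 1L
      return(rgs)
    }
  }
  NULL
}

oracle_best_partition_Q <- function(a) {
  best <- -Inf
  rgs <- rep(1L, nrow(a))
  repeat {
    q <- oracle_modularity(a, rgs)
    if (q > best) best <- q
    rgs <- next_rgs(rgs)
    if (is.null(rgs)) break
  }
  best
}

# adjusted Rand index between two labelings (contingency-table formula)
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
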