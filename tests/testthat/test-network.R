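# Network construction and topology metrics, validated against the
# brute-force oracles in helper-oracles.R.

toy_edges <- function() {
  data.frame(from = c("a", "a", "b", "c"),
             to = c("b", "c", "c", "d"),
             rho = c(0.9, 0.8, -0.7, 0.65),
             p = c(1e-4, 1e-3, 2e-3, 5e-3),
             sign = c(1L, 1L, -1L, 1L),
             weight = c(0.9, 0.8, 0.7, 0.65),
             stringsAsFactors = FALSE)
}

two_triangles <- function() {
  e <- data.frame(from = c("a", "a", "b", "x", "x", "y"),
                  to = c("b", "c", "c", "y", "z", "z"))
  e$rho <- 0.9; e$p <- 1e-4; e$sign <- 1L; e$weight <- 0.9
  build_network(e)
}

test_that("build_network assembles a simple signed graph", {
  g <- build_network(toy_edges(),
                     node_abundance = c(a = 0.2, b = 0.1, c = 0.05,
                                        d = 0.01, e = 0.3),
                     group = "ambient")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 4)
  expect_equal(igraph::graph_attr(g, "group"), "ambient")
  expect_equal(igraph::graph_attr(g, "isolated"), "e")
  expect_equal(sort(igraph::E(g)$sign), c(-1L, 1L, 1L, 1L))
  # duplicate pair collapses; conflicting sign errors
  dup <- rbind(toy_edges(), toy_edges()[1, ])
  expect_equal(igraph::ecount(build_network(dup)), 4)
  conflict <- rbind(toy_edges(),
                    data.frame(from = "b", to = "a", rho = -0.7, p = 1e-3,
                               sign = -1L, weight = 0.7))
  expect_error(build_network(conflict), "conflicting signs")
  expect_warning(g0 <- build_network(toy_edges()[0, ]), "no edges")
  expect_equal(igraph::vcount(g0), 0)
})

test_that("clustering coefficient: closed forms and brute-force oracle", {
  tri <- graph_from_adj(matrix(1, 3, 3) - diag(3))
  expect_equal(clustering_coefficient(tri), 1)
  star <- graph_from_adj(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
                               c(1, 0, 0, 0), c(1, 0, 0, 0)))
  expect_equal(clustering_coefficient(star), 0)
  set.seed(51)
  for (i in 1:30) {
    a <- random_adjacency(sample(4:12, 1), runif(1, 0.2, 0.7))
    g <- graph_from_adj(a)
    expect_equal(clustering_coefficient(g), oracle_cc(a))
  }
})

test_that("average path length: closed forms and Floyd-Warshall oracle", {
  p3 <- graph_from_adj(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(as.numeric(average_path_length(p3)), 4 / 3)
  k5 <- graph_from_adj(matrix(1, 5, 5) - diag(5))
  expect_equal(as.numeric(average_path_length(k5)), 1)
  set.seed(52)
  for (i in 1:30) {
    a <- random_adjacency(sample(4:12, 1), runif(1, 0.15, 0.6))
    if (sum(a) == 0) next
    g <- graph_from_adj(a)
    expect_equal(as.numeric(average_path_length(g)), oracle_apl(a))
  }
})

test_that("betweenness: symmetry cases and path-enumeration oracle", {
  star5 <- graph_from_adj(rbind(c(0, 1, 1, 1, 1), cbind(1, matrix(0, 4, 4))))
  bs <- betweenness_stats(star5)
  expect_equal(unname(bs$normalized_betweenness[1]), 1)
  expect_equal(unname(bs$normalized_betweenness[-1]), rep(0, 4))
  c5 <- graph_from_adj(local({
    a <- matrix(0, 5, 5)
    for (i in 1:5) a[i, i %% 5 + 1] <- 1
    a + t(a)
  }))
  nb <- betweenness_stats(c5)$normalized_betweenness
  expect_true(all(abs(nb - nb[1]) < 1e-12))
  set.seed(53)
  for (i in 1:25) {
    n <- sample(5:9, 1)
    a <- random_adjacency(n, runif(1, 0.25, 0.6))
    g <- graph_from_adj(a)
    norm <- (n - 1) * (n - 2) / 2
    expect_equal(unname(betweenness_stats(g)$normalized_betweenness),
                 oracle_betweenness(a) / norm)
  }
})

test_that("degree stats: closed forms and identities", {
  k4 <- graph_from_adj(matrix(1, 4, 4) - diag(4))
  ds <- degree_stats(k4)
  expect_equal(ds$average_degree, 3)
  expect_equal(ds$average_normalized_degree, 1)
  star5 <- graph_from_adj(rbind(c(0, 1, 1, 1, 1), cbind(1, matrix(0, 4, 4))))
  expect_equal(degree_stats(star5)$average_normalized_degree,
               (1 + 4 * 0.25) / 5)
  set.seed(54)
  for (i in 1:20) {
    a <- random_adjacency(sample(4:12, 1), 0.4)
    g <- graph_from_adj(a)
    ds <- degree_stats(g)
    expect_equal(unname(ds$degree), rowSums(a), ignore_attr = TRUE)
    expect_equal(ds$average_degree,
                 2 * igraph::ecount(g) / igraph::vcount(g))
    expect_equal(ds$average_normalized_degree,
                 ds$average_degree / (nrow(a) - 1))
  }
})

test_that("modularity: scoring matches Q formula; greedy finds good partitions", {
  g2 <- two_triangles()
  part <- modularity_partition(g2)
  expect_equal(part$modularity, 0.5)
  expect_equal(length(unique(part$membership)), 2)
  # the two triangles are exactly the modules
  memb <- part$membership
  expect_equal(length(unique(memb[c("a", "b", "c")])), 1)
  expect_equal(length(unique(memb[c("x", "y", "z")])), 1)
  expect_true(memb["a"] != memb["x"])
  # all-in-one partition scores Q = 0
  a2 <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
  expect_equal(oracle_modularity(a2, rep(1, 6)), 0)

  # ring of 3 cliques: each clique is one module
  blocks <- kronecker(diag(3), matrix(1, 4, 4) - diag(4))
  blocks[1, 5] <- blocks[5, 1] <- 1
  blocks[6, 9] <- blocks[9, 6] <- 1
  blocks[10, 2] <- blocks[2, 10] <- 1
  gr <- graph_from_adj(blocks[1:12, 1:12])
  pr <- modularity_partition(gr)
  expect_equal(length(unique(pr$membership)), 3)
  truth <- rep(1:3, each = 4)
  expect_equal(oracle_ari(pr$membership, truth), 1)

  # returned Q agrees with the hand Q formula on random graphs, and beats
  # the trivial partition
  set.seed(55)
  for (i in 1:20) {
    a <- random_adjacency(sample(5:10, 1), 0.4)
    if (sum(a) == 0) next
    g <- graph_from_adj(a)
    p <- modularity_partition(g)
    expect_equal(p$modularity,
                 oracle_modularity(a, p$membership[igraph::V(g)$name]))
    expect_gte(p$modularity, 0)
  }
})

test_that("greedy modularity attains the exhaustive-search optimum on tiny graphs", {
  set.seed(56)
  n_match <- 0L
  n_total <- 40L
  for (i in seq_len(n_total)) {
    a <- random_adjacency(sample(5:8, 1), runif(1, 0.3, 0.6))
    if (sum(a) == 0) {
      n_match <- n_match + 1L
      next
    }
    g <- graph_from_adj(a)
    p <- modularity_partition(g)
    best <- oracle_best_partition_Q(a)
    if (abs(p$modularity - best) < 1e-9) n_match <- n_match + 1L
  }
  expect_gte(n_match / n_total, 0.95)
})

test_that("positive ratio counts signed edges", {
  g <- build_network(toy_edges())
  expect_equal(positive_ratio(g), 0.75)
  e <- toy_edges(); e$sign <- 1L
  expect_equal(positive_ratio(build_network(e)), 1)
  e$sign <- c(1L, 1L, -1L, -1L)
  expect_equal(positive_ratio(build_network(e)), 0.5)
})

test_that("Erdos-Renyi baseline approaches the edge density", {
  n <- 100
  p <- 0.15
  m <- round(p * n * (n - 1) / 2)
  rb <- random_baseline(n = n, m = m, n_reps = 50, seed = 7)
  expect_equal(rb$mean, p, tolerance = 0.1)
  expect_equal(random_baseline(n = 10, m = 0, n_reps = 3, seed = 1)$mean, 0)
  expect_equal(random_baseline(n = 6, m = 15, n_reps = 3, seed = 1)$mean, 1)
  # determinism under a fixed seed
  expect_identical(random_baseline(n = 30, m = 60, n_reps = 10, seed = 3),
                   random_baseline(n = 30, m = 60, n_reps = 10, seed = 3))
})

test_that("power-law fit recovers a planted exponent and rejects flat degrees", {
  set.seed(57)
  # exact zeta(alpha = 2.5) sample via inverse CDF
  alpha <- 2.5
  xs <- 1:100000
  cdf <- cumsum(xs^(-alpha)) / sum(xs^(-alpha))
  draw <- findInterval(runif(2000, 0, max(cdf)), cdf) + 1
  fit <- powerlaw_fit(draw, n_boot = 0)
  expect_gte(fit$alpha, 2.3)
  expect_lte(fit$alpha, 2.7)
  # goodness-of-fit bootstrap does not reject the true model
  fit_p <- powerlaw_fit(draw[1:500], n_boot = 60, seed = 2)
  expect_gt(fit_p$p_value, 0.05)
  # near-constant degree sequence is rejected
  flat <- rep(c(6L, 7L), each = 150)
  expect_warning(fit_flat <- powerlaw_fit(flat, n_boot = 60, seed = 3),
                 "distinct degree")
  expect_lt(fit_flat$p_value, 0.05)
})

test_that("topology panel assembles all metrics deterministically", {
  g2 <- two_triangles()
  panel <- topology_panel(g2, n_reps = 20, seed = 9)
  expect_equal(panel$clustering_coefficient, 1)
  expect_equal(panel$modularity, 0.5)
  expect_equal(panel$average_path_length, 1)
  expect_equal(panel$average_degree, 2)
  expect_equal(panel$average_normalized_degree, 2 / 5)
  expect_equal(panel$positive_ratio, 1)
  expect_equal(panel$order, 6)
  expect_equal(panel$size, 6)
  panel2 <- topology_panel(g2, n_reps = 20, seed = 9)
  expect_identical(panel, panel2)
  expect_error(topology_panel(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("networks round-trip through GraphML and edge-list TSV", {
  g <- build_network(toy_edges(), node_abundance = c(a = 0.2, b = 0.1,
                                                     c = 0.05, d = 0.01))
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(g, graphml_path = f1, edges_path = f2)
  back <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::vcount(back), 4)
  expect_equal(igraph::ecount(back), 4)
  expect_setequal(igraph::E(back)$sign, igraph::E(g)$sign)
  edges <- utils::read.delim(f2)
  expect_equal(nrow(edges), 4)
  expect_true(all(c("from", "to", "rho", "p", "sign", "weight")
                  %in% names(edges)))
})
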