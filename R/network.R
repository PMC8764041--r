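#' Build a co-occurrence network from a kept-edge list
#'
#' Assembles an undirected simple igraph object from the output of
#' [select_edges()]. Edge attributes `rho`, `p`, `sign` and `weight`
#' (= |rho|) are kept; node attributes `abundance` (mean relative abundance
#' over the group's samples) and `lineage` are attached when supplied.
#' Taxa present in `node_abundance` but without any kept edge are omitted
#' from the graph and listed in the `"isolated"` graph attribute.
#'
#' @param edges Data frame with columns `from`, `to`, `rho`, `p`, `sign`,
#'   `weight`.
#' @param node_abundance Optional named numeric vector of mean relative
#'   abundances.
#' @param lineage Optional named character vector of lineage strings.
#' @param group Optional group label stored as a graph attribute.
#' @return An `igraph` object.
#' @export
build_network <- function(edges, node_abundance = NULL, lineage = NULL,
                          group = NULL) {
  if (nrow(edges) == 0) {
    warning("no edges passed the thresholds: returning an empty graph")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_graph_attr(g, "group", group %||% NA_character_)
    return(g)
  }
  key <- ifelse(edges$from < edges$to,
                paste(edges$from, edges$to, sep = "\r"),
                paste(edges$to, edges$from, sep = "\r"))
  if (anyDuplicated(key)) {
    split_sign <- tapply(edges$sign, key, function(s) length(unique(s)))
    if (any(split_sign > 1))
      stop("conflicting signs for a duplicated taxon pair", call. = FALSE)
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  if (any(edges$from == edges$to))
    stop("self-correlation edges are not allowed", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(node_abundance)) {
    igraph::V(g)$abundance <-
      unname(node_abundance[igraph::V(g)$name])
    isolated <- setdiff(names(node_abundance), igraph::V(g)$name)
    g <- igraph::set_graph_attr(g, "isolated", isolated)
  }
  if (!is.null(lineage))
    igraph::V(g)$lineage <- unname(lineage[igraph::V(g)$name])
  g <- igraph::set_graph_attr(g, "group", group %||% NA_character_)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average local clustering coefficient
#'
#' Mean over nodes of the local transitivity (triangles through a node
#' divided by the number of possible neighbour pairs), computed on the
#' unweighted, sign-agnostic skeleton. Nodes with fewer than two neighbours
#' contribute 0. The global-transitivity convention (triangle ratio over
#' the whole graph) is available via `type = "global"`.
#'
#' @param g An igraph object.
#' @param type `"local"` (default, mean local coefficient) or `"global"`.
#' @return Clustering coefficient in \[0, 1\].
#' @export
clustering_coefficient <- function(g, type = c("local", "global")) {
  type <- match.arg(type)
  if (type == "global") return(igraph::transitivity(g, type = "global"))
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Community detection and modularity
#'
#' Partitions the unweighted, sign-agnostic skeleton into modules and
#' returns Newman-Girvan modularity
#' \eqn{Q = \sum_c (e_c/m - (d_c/2m)^2)}. The default `"greedy"` method is
#' fully deterministic: graphs of at most `exact_max` nodes are solved to
#' the exact modularity optimum (integer programming via
#' [igraph::cluster_optimal()], cheap at that scale); larger graphs use
#' greedy agglomeration followed by a deterministic local-move refinement
#' (each vertex is offered to its neighbours' communities, or a fresh
#' singleton, and moved whenever Q strictly increases, sweeping until no
#' move helps). Louvain is available with a seed for its randomised
#' ordering.
#'
#' @param g An igraph object with at least one edge.
#' @param method `"greedy"` (default), `"louvain"`, or `"optimal"` (exact,
#'   only sensible for small graphs).
#' @param exact_max Node-count limit below which `"greedy"` switches to the
#'   exact optimum (default 12).
#' @param seed Integer seed for randomised methods.
#' @return List with `membership` (named integer vector), `modularity`
#'   (Q of the partition) and `method`.
#' @export
modularity_partition <- function(g, method = c("greedy", "louvain", "optimal"),
                                 seed = 1L, exact_max = 12L) {
  method <- match.arg(method)
  if (igraph::ecount(g) == 0)
    stop("cannot detect communities in an edgeless graph", call. = FALSE)
  gs <- .skeleton(g)
  if (method == "greedy" && igraph::vcount(gs) <= exact_max)
    method <- "optimal"
  membership <- if (method == "optimal") {
    as.integer(igraph::membership(igraph::cluster_optimal(gs)))
  } else if (method == "greedy") {
    m0 <- igraph::membership(igraph::cluster_fast_greedy(gs))
    .refine_partition(gs, as.integer(m0))
  } else {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    as.integer(igraph::membership(igraph::cluster_louvain(gs)))
  }
  nms <- igraph::V(g)$name
  list(membership = structure(membership, names = nms),
       modularity = igraph::modularity(gs, membership),
       method = method)
}

# first-improvement hill climbing on modularity: offer each vertex to each
# neighbouring community (ascending id, so the sweep is deterministic)
.refine_partition <- function(gs, membership) {
  adj <- igraph::as_adj_list(gs)
  repeat {
    improved <- FALSE
    for (v in seq_along(membership)) {
      q0 <- igraph::modularity(gs, membership)
      # neighbouring communities, plus splitting off as a fresh singleton
      cands <- c(sort(unique(membership[as.integer(adj[[v]])])),
                 max(membership) + 1L)
      for (cand in cands) {
        if (cand == membership[v]) next
        trial <- membership
        trial[v] <- cand
        if (igraph::modularity(gs, trial) > q0 + 1e-12) {
          membership <- trial
          q0 <- igraph::modularity(gs, membership)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  membership
}

# unweighted, sign-agnostic copy used for all topology metrics
.skeleton <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  g
}

#' Average shortest path length
#'
#' Mean unweighted shortest-path length over all connected ordered pairs.
#' Pairs in different components are excluded from the average (component
#' sizes are attached as an attribute for inspection).
#'
#' @param g An igraph object.
#' @return Average path length, with attribute `"components"` giving
#'   component sizes.
#' @export
average_path_length <- function(g) {
  apl <- igraph::mean_distance(.skeleton(g), directed = FALSE,
                               unconnected = TRUE)
  attr(apl, "components") <- igraph::components(g)$csize
  apl
}

#' Fraction of positive edges
#'
#' @param g An igraph object whose edges carry a `sign` attribute (+1/-1).
#' @return Proportion of edges with positive sign.
#' @export
positive_ratio <- function(g) {
  s <- igraph::E(g)$sign
  if (is.null(s)) stop("edges carry no 'sign' attribute", call. = FALSE)
  mean(s > 0)
}

#' Average degree and normalized degree
#'
#' Normalized degree divides each node's degree by `order - 1`, the maximum
#' possible, giving values in \[0, 1\] comparable across networks of
#' different size.
#'
#' @param g An igraph object.
#' @return List with `average_degree`, `average_normalized_degree`, and the
#'   per-node vectors `degree` and `normalized_degree`.
#' @export
degree_stats <- function(g) {
  k <- igraph::degree(g)
  n <- igraph::vcount(g)
  nk <- if (n > 1) k / (n - 1) else k * NA_real_
  list(average_degree = mean(k),
       average_normalized_degree = mean(nk),
       degree = k,
       normalized_degree = nk)
}

#' Betweenness centrality, normalized
#'
#' Shortest-path betweenness on the unweighted skeleton, endpoints
#' excluded, divided by \eqn{(n-1)(n-2)/2} — the number of node pairs a
#' vertex of an undirected graph could lie between.
#'
#' @param g An igraph object.
#' @return List with `average_normalized_betweenness` and the per-node
#'   vector `normalized_betweenness`.
#' @export
betweenness_stats <- function(g) {
  nb <- igraph::betweenness(.skeleton(g), directed = FALSE,
                            normalized = TRUE)
  list(average_normalized_betweenness = mean(nb),
       normalized_betweenness = nb)
}

#' Erdős–Rényi clustering-coefficient baseline
#'
#' Generates `n_reps` G(n, m) random graphs with the same order and size as
#' `g` and returns the mean and standard deviation of their clustering
#' coefficients. For G(n, m) the expectation approaches the edge density
#' 2m / (n(n-1)).
#'
#' @param g An igraph object (or `NULL` if `n` and `m` are given).
#' @param n_reps Number of replicate random graphs (default 100).
#' @param seed Integer seed.
#' @param n,m Order and size, taken from `g` when omitted.
#' @return List with `mean`, `sd`, `n_reps`.
#' @export
random_baseline <- function(g = NULL, n_reps = 100, seed = 1L,
                            n = NULL, m = NULL) {
  if (is.null(n)) n <- igraph::vcount(g)
  if (is.null(m)) m <- igraph::ecount(g)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ccs <- replicate(n_reps, {
    gr <- igraph::sample_gnm(n, m)
    igraph::transitivity(gr, type = "localaverage", isolates = "zero")
  })
  list(mean = mean(ccs), sd = stats::sd(ccs), n_reps = n_reps)
}

#' Discrete power-law fit of a degree sequence
#'
#' Maximum-likelihood exponent of a discrete power law fitted to the tail
#' of the degree distribution, with `x_min` chosen by minimising the
#' Kolmogorov-Smirnov distance (or supplied). The goodness-of-fit p-value
#' is obtained by parametric bootstrap: synthetic degree samples are drawn
#' from the fitted power law (with the empirical distribution below
#' `x_min`), refitted, and their KS distances compared with the observed
#' one. Small p rejects the power law.
#'
#' @param degrees Integer vector of node degrees (values < 1 are dropped).
#' @param x_min Fixed lower cut-off; `NULL` (default) selects it by KS
#'   minimisation.
#' @param n_boot Bootstrap replicates for the goodness-of-fit p (default
#'   100; 0 skips the bootstrap and returns `NA` p).
#' @param seed Integer seed for the bootstrap.
#' @return List with `alpha`, `x_min`, `ks_stat`, `p_value`, `n_tail`.
#' @export
powerlaw_fit <- function(degrees, x_min = NULL, n_boot = 100, seed = 1L) {
  degrees <- degrees[degrees >= 1]
  if (length(unique(degrees)) < 10)
    warning("fewer than 10 distinct degree values: power-law fit is fragile")
  fit <- igraph::fit_power_law(degrees, xmin = x_min,
                               implementation = "plfit")
  alpha <- fit$alpha
  xmin <- fit$xmin
  ks <- fit$KS.stat
  p <- NA_real_
  if (n_boot > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    n <- length(degrees)
    below <- degrees[degrees < xmin]
    p_tail <- mean(degrees >= xmin)
    ks_boot <- replicate(n_boot, {
      tail_draw <- stats::rbinom(1, n, p_tail)
      syn <- c(sample(below, n - tail_draw, replace = TRUE),
               .sample_discrete_powerlaw(tail_draw, alpha, xmin))
      bf <- igraph::fit_power_law(syn, implementation = "plfit")
      bf$KS.stat
    })
    p <- mean(ks_boot >= ks)
  }
  list(alpha = alpha, x_min = xmin, ks_stat = ks, p_value = p,
       n_tail = sum(degrees >= xmin))
}

# inverse-CDF sampler for P(X = x) proportional to x^-alpha, x >= xmin
.sample_discrete_powerlaw <- function(n, alpha, xmin, xmax = 1e6) {
  if (n == 0) return(integer(0))
  # continuous approximation then rounding, standard for bootstrap draws
  u <- stats::runif(n)
  floor((xmin - 0.5) * (1 - u)^(-1 / (alpha - 1)) + 0.5)
}

#' Topology panel for one network
#'
#' Assembles the network-level summary used to compare groups: clustering
#' coefficient, random-graph baseline clustering coefficient, modularity,
#' positive ratio, average path length, average degree, average normalized
#' degree, average normalized betweenness, order and size. Deterministic
#' given `seed`.
#'
#' @param g An igraph object with at least one edge.
#' @param n_reps Random-baseline replicates.
#' @param seed Integer seed (random baseline, community detection).
#' @param method Community detection method, see [modularity_partition()].
#' @return One-row data frame (plus a `"membership"` attribute carrying the
#'   module partition used).
#' @export
topology_panel <- function(g, n_reps = 100, seed = 1L, method = "greedy") {
  if (igraph::vcount(g) == 0 || igraph::ecount(g) == 0)
    stop("topology panel undefined for an empty graph", call. = FALSE)
  part <- modularity_partition(g, method = method, seed = seed)
  ds <- degree_stats(g)
  bs <- betweenness_stats(g)
  rb <- random_baseline(g, n_reps = n_reps, seed = seed)
  out <- data.frame(
    group = igraph::graph_attr(g, "group") %||% NA_character_,
    clustering_coefficient = clustering_coefficient(g),
    random_clustering_coefficient = rb$mean,
    modularity = part$modularity,
    positive_ratio = if (is.null(igraph::E(g)$sign)) NA_real_
                     else positive_ratio(g),
    average_path_length = as.numeric(average_path_length(g)),
    average_degree = ds$average_degree,
    average_normalized_degree = ds$average_normalized_degree,
    average_normalized_betweenness = bs$average_normalized_betweenness,
    order = igraph::vcount(g),
    size = igraph::ecount(g),
    stringsAsFactors = FALSE)
  attr(out, "membership") <- part$membership
  out
}

#' Write a network as GraphML and/or edge-list TSV
#'
#' @param g An igraph object.
#' @param graphml_path,edges_path Output paths (`NULL` skips).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(g, graphml_path = NULL, edges_path = NULL) {
  written <- character(0)
  if (!is.null(graphml_path)) {
    # GraphML attributes must be scalar: flatten vectors, blank NAs
    for (a in igraph::graph_attr_names(g)) {
      val <- igraph::graph_attr(g, a)
      if (length(val) != 1L)
        g <- igraph::set_graph_attr(g, a, paste(val, collapse = ","))
      else if (is.na(val))
        g <- igraph::set_graph_attr(g, a, "")
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(edges_path)) {
    df <- igraph::as_data_frame(g, what = "edges")
    utils::write.table(df, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, edges_path)
  }
  invisible(written)
}
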