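#' Within-module and among-module connectivity (Zi, Pi)
#'
#' For every node of a modular network, computes the within-module degree
#' z-score and the among-module participation coefficient:
#' \deqn{Z_i = (\kappa_i - \bar{\kappa}_{m(i)}) / \sigma_{\kappa, m(i)}}
#' \deqn{P_i = 1 - \sum_s (k_{is} / k_i)^2}
#' where \eqn{\kappa_i} is the number of links node i makes inside its own
#' module, the mean and standard deviation run over that module's members
#' (population sd), and \eqn{k_{is}} counts links from i into module s
#' (including i's own module). Modules whose within-degree sd is zero (e.g.
#' singleton or perfectly regular modules) get \eqn{Z_i = 0}, flagged in
#' `degenerate_z`.
#'
#' @param g An igraph object.
#' @param membership Module partition: named integer vector as returned in
#'   [modularity_partition()]`$membership`. Taken from the graph attribute
#'   `membership` if missing.
#' @return Data frame, one row per node: `taxon`, `module`, `degree`,
#'   `within_module_degree`, `Zi`, `Pi`, `normalized_degree`,
#'   `normalized_betweenness`, `abundance` (NA when the graph carries no
#'   abundance attribute), `degenerate_z`.
#' @export
zi_pi <- function(g, membership = NULL) {
  if (is.null(membership))
    membership <- igraph::graph_attr(g, "membership")
  if (is.null(membership))
    stop("no module partition: pass 'membership' or run ",
         "modularity_partition() first", call. = FALSE)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  if (!all(nodes %in% names(membership)))
    stop("membership must cover every node", call. = FALSE)
  memb <- membership[nodes]
  adj <- igraph::as_adj_list(g)
  k <- igraph::degree(g)
  n <- length(nodes)

  kappa <- numeric(n)       # links into own module
  pi_coef <- numeric(n)
  for (v in seq_len(n)) {
    nb <- as.integer(adj[[v]])
    if (length(nb) == 0) next
    mods <- memb[nb]
    kappa[v] <- sum(mods == memb[v])
    k_is <- table(mods)
    pi_coef[v] <- 1 - sum((as.numeric(k_is) / k[v])^2)
  }

  z <- numeric(n)
  degenerate <- logical(n)
  for (m in unique(memb)) {
    idx <- which(memb == m)
    mu <- mean(kappa[idx])
    sdev <- sqrt(mean((kappa[idx] - mu)^2))   # population sd
    if (sdev > 0) {
      z[idx] <- (kappa[idx] - mu) / sdev
    } else {
      z[idx] <- 0
      degenerate[idx] <- TRUE
    }
  }

  nd <- if (n > 1) k / (n - 1) else k * NA_real_
  nb <- betweenness_stats(g)$normalized_betweenness
  ab <- igraph::V(g)$abundance
  data.frame(taxon = nodes,
             module = as.integer(memb),
             degree = as.integer(k),
             within_module_degree = as.integer(kappa),
             Zi = z,
             Pi = pi_coef,
             normalized_degree = unname(nd),
             normalized_betweenness = unname(nb),
             abundance = if (is.null(ab)) NA_real_ else ab,
             degenerate_z = degenerate,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify nodes into ecological roles from (Zi, Pi)
#'
#' The classical four quadrants: peripherals (low Zi, low Pi), module hubs
#' (high Zi, low Pi), connectors (low Zi, high Pi) and network hubs (high
#' both). The default thresholds 2.5 and 0.62 are the widely used
#' convention for these plots; both are exposed because published analyses
#' occasionally adjust them.
#'
#' @param nodes Data frame from [zi_pi()].
#' @param z_threshold Zi cut-off separating hubs (default 2.5).
#' @param p_threshold Pi cut-off separating connectors (default 0.62).
#' @return `nodes` with an added `role` factor
#'   (peripheral / module_hub / connector / network_hub).
#' @export
classify_roles <- function(nodes, z_threshold = 2.5, p_threshold = 0.62) {
  stopifnot(all(c("Zi", "Pi") %in% names(nodes)))
  hi_z <- nodes$Zi > z_threshold
  hi_p <- nodes$Pi > p_threshold
  role <- ifelse(hi_z & hi_p, "network_hub",
          ifelse(hi_z, "module_hub",
          ifelse(hi_p, "connector", "peripheral")))
  nodes$role <- factor(role, levels = c("peripheral", "module_hub",
                                        "connector", "network_hub"))
  attr(nodes, "thresholds") <- c(z = z_threshold, p = p_threshold)
  nodes
}

#' Rank central hubs and gatekeepers
#'
#' Returns the `top_n` nodes by normalized degree (central hubs) and by
#' normalized betweenness (gatekeepers), with deterministic ordering (ties
#' broken lexically by taxon id) and the overlap between the two lists.
#'
#' @param nodes Data frame from [zi_pi()].
#' @param top_n List length (default 10; truncated to the node count).
#' @return List with data frames `by_degree` and `by_betweenness`, and
#'   `shared` — taxa appearing in both top lists.
#' @export
rank_hubs <- function(nodes, top_n = 10) {
  stopifnot(all(c("taxon", "normalized_degree", "normalized_betweenness")
                %in% names(nodes)))
  top_n <- min(top_n, nrow(nodes))
  by_deg <- nodes[order(-nodes$normalized_degree, nodes$taxon), ]
  by_bet <- nodes[order(-nodes$normalized_betweenness, nodes$taxon), ]
  by_deg <- utils::head(by_deg, top_n)
  by_bet <- utils::head(by_bet, top_n)
  rownames(by_deg) <- rownames(by_bet) <- NULL
  list(by_degree = by_deg,
       by_betweenness = by_bet,
       shared = intersect(by_deg$taxon, by_bet$taxon))
}

#' Association between abundance and node centrality
#'
#' Tests whether a taxon's mean relative abundance predicts its centrality,
#' using Spearman rank correlation of abundance against normalized degree
#' and normalized betweenness. Low-abundance taxa (below
#' `low_abundance`) occurring in the top `top_n` of either centrality
#' ranking are listed — the interesting case being rare taxa holding
#' central positions.
#'
#' @param nodes Data frame from [zi_pi()] with a non-NA `abundance` column.
#' @param low_abundance Relative-abundance threshold flagging "rare"
#'   (default 0.01 = 1%).
#' @param top_n Rank depth used for the rare-central flag (default 10).
#' @return List with `tests` (data frame: metric, rho, p) and
#'   `rare_central` (taxa below the threshold inside a top list).
#' @export
abundance_role_association <- function(nodes, low_abundance = 0.01,
                                       top_n = 10) {
  if (nrow(nodes) < 2)
    stop("need at least two nodes to correlate", call. = FALSE)
  if (all(is.na(nodes$abundance)))
    stop("nodes carry no abundance values", call. = FALSE)
  test_one <- function(y) {
    ct <- suppressWarnings(
      stats::cor.test(nodes$abundance, y, method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  td <- test_one(nodes$normalized_degree)
  tb <- test_one(nodes$normalized_betweenness)
  hubs <- rank_hubs(nodes, top_n = top_n)
  top_taxa <- union(hubs$by_degree$taxon, hubs$by_betweenness$taxon)
  rare <- nodes$taxon[!is.na(nodes$abundance) &
                        nodes$abundance < low_abundance]
  list(tests = data.frame(
         metric = c("normalized_degree", "normalized_betweenness"),
         rho = c(td["rho"], tb["rho"]),
         p = c(td["p"], tb["p"]),
         row.names = NULL),
       rare_central = intersect(top_taxa, rare))
}

#' Write node-level topology and role tables
#'
#' @param nodes Data frame from [zi_pi()] / [classify_roles()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(nodes, path) {
  utils::write.table(nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
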