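#' All-pairs Spearman correlation with significance
#'
#' Computes Spearman's rank correlation for every taxon pair of a
#' (filtered) samples x taxa table. Ties receive mid-ranks; the coefficient
#' is the Pearson correlation of the rank vectors. Two-sided p-values come
#' from the t statistic \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2}
#' degrees of freedom; \eqn{|\rho| = 1} is reported as p = 0. The t
#' approximation is slightly anticonservative for very small n (realised
#' pairwise rejection around 1.3% at a nominal 1% for n = 10), so two
#' permutation alternatives are provided: `p_method = "exact"` enumerates
#' all n! orderings (n <= 8), and `p_method = "sampled"` draws `n_perm`
#' random column shuffles (any n; calibrated by construction, with the
#' usual +1 correction).
#'
#' Taxa with zero variance across samples have no defined rank correlation;
#' they are flagged in `$excluded` and their rows/columns are set `NA` so
#' they can never become edge candidates.
#'
#' @param table Samples x taxa numeric matrix with at least 4 samples.
#' @param p_method `"t"` (default), `"exact"` or `"sampled"`.
#' @param n_perm Random shuffles for `p_method = "sampled"` (default 1999).
#' @param perm_seed Seed for the random shuffles (default 1).
#' @return An object of class `co_correlation`: list with `rho` and `p`
#'   (taxa x taxa matrices, `NA` diagonal), `n` (samples used), `excluded`
#'   (constant taxa), and `p_method`.
#' @export
spearman_matrix <- function(table, p_method = c("t", "exact", "sampled"),
                            n_perm = 1999, perm_seed = 1L) {
  p_method <- match.arg(p_method)
  m <- as.matrix(table)
  n <- nrow(m)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  constant <- apply(m, 2, function(x) length(unique(x)) == 1L)
  ranks <- apply(m, 2, rank)   # mid-ranks for ties
  rho <- suppressWarnings(stats::cor(ranks))
  rho[, constant] <- NA_real_
  rho[constant, ] <- NA_real_
  if (p_method == "t") {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(rho) >= 1 - 1e-12] <- 0
  } else if (p_method == "sampled") {
    p <- .spearman_sampled_p(ranks, rho, n_perm, perm_seed)
  } else {
    if (n > 8L)
      stop("exact permutation p-values enumerate n! orderings; ",
           "limited to n <= 8 samples", call. = FALSE)
    p <- .spearman_exact_p(ranks, rho)
  }
  diag(rho) <- NA_real_
  diag(p) <- NA_real_
  structure(list(rho = rho, p = p, n = n,
                 excluded = colnames(m)[constant],
                 p_method = p_method),
            class = "co_correlation")
}

# Monte-Carlo permutation p: every replicate shuffles each column's ranks
# independently (preserving tie patterns) and correlates all pairs at once,
# so each pair accumulates n_perm draws from its own permutation null.
.spearman_sampled_p <- function(ranks, rho, n_perm, perm_seed) {
  n <- nrow(ranks)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(perm_seed)
  obs <- abs(rho)
  hits <- matrix(0, nrow(rho), ncol(rho))
  for (b in seq_len(n_perm)) {
    shuffled <- apply(ranks, 2, sample, size = n)
    null_rho <- suppressWarnings(stats::cor(shuffled))
    hits <- hits + (abs(null_rho) >= obs - 1e-12)
  }
  p <- (1 + hits) / (n_perm + 1)
  p[is.na(rho)] <- NA_real_
  p
}

# Exact two-sided permutation p for every pair: for each pair (i, j), the
# null distribution is rho over all n! orderings of one rank vector with the
# other held fixed (correct under ties because the observed tie patterns are
# preserved).
.spearman_exact_p <- function(ranks, rho) {
  n <- nrow(ranks)
  perms <- .all_permutations(n)       # n! x n index matrix
  p <- rho
  p[] <- NA_real_
  nt <- ncol(ranks)
  centred <- scale(ranks, center = TRUE, scale = FALSE)
  sds <- apply(ranks, 2, stats::sd)
  for (i in seq_len(nt - 1L)) {
    if (sds[i] == 0) next
    xi <- centred[, i]
    for (j in (i + 1L):nt) {
      if (sds[j] == 0) next
      yj <- ranks[, j]
      perm_y <- matrix(yj[perms], nrow = nrow(perms))
      # sum(xi) == 0, so centring yj is unnecessary in the cross product
      null_rho <- (perm_y %*% xi) / ((n - 1) * sds[i] * sds[j])
      obs <- abs(rho[i, j])
      p[i, j] <- p[j, i] <- mean(abs(null_rho) >= obs - 1e-12)
    }
  }
  p
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    remap <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(remap[sub], nrow = nrow(sub))
  }
  out
}

#' Select significant correlation edges
#'
#' Applies the network construction thresholds: an edge is kept when
#' \eqn{|\rho|} exceeds `r_min` \emph{and} p is below `p_max` (defaults 0.6
#' and 0.01). The absolute-value reading admits negative associations, which
#' co-occurrence networks of digesters do contain; `mode = "positive"`
#' restricts to positive coefficients for sensitivity analysis.
#'
#' @param corr A [spearman_matrix()] result.
#' @param r_min Correlation magnitude threshold (strict `>`).
#' @param p_max Significance threshold (strict `<`), on raw p-values by
#'   default.
#' @param mode `"absolute"` (default) or `"positive"`.
#' @param adjust_p If `TRUE`, apply Benjamini-Hochberg correction across all
#'   distinct pairs before thresholding (off by default: raw p-values are
#'   the conventional choice for these networks).
#' @return Data frame with columns `from`, `to`, `rho`, `p`, `sign`
#'   (+1/-1) and `weight` (= |rho|), one row per kept edge.
#' @export
select_edges <- function(corr, r_min = 0.6, p_max = 0.01,
                         mode = c("absolute", "positive"),
                         adjust_p = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(corr, "co_correlation"))
  rho <- corr$rho
  p <- corr$p
  taxa <- colnames(rho)
  if (is.null(taxa)) taxa <- as.character(seq_len(ncol(rho)))
  ut <- upper.tri(rho)
  idx <- which(ut, arr.ind = TRUE)
  r <- rho[ut]
  pv <- p[ut]
  if (adjust_p) pv <- stats::p.adjust(pv, method = "BH")
  keep <- !is.na(r) & !is.na(pv) & pv < p_max &
    (if (mode == "absolute") abs(r) > r_min else r > r_min)
  data.frame(from = taxa[idx[keep, 1]],
             to = taxa[idx[keep, 2]],
             rho = r[keep],
             p = pv[keep],
             sign = ifelse(r[keep] >= 0, 1L, -1L),
             weight = abs(r[keep]),
             stringsAsFactors = FALSE)
}

#' Write a correlation matrix and kept-edge list
#'
#' @param corr A [spearman_matrix()] result.
#' @param edges A [select_edges()] data frame.
#' @param rho_path,edges_path Output TSV paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_correlation <- function(corr, edges = NULL, rho_path = NULL,
                              edges_path = NULL) {
  written <- character(0)
  if (!is.null(rho_path)) {
    df <- data.frame(taxon = rownames(corr$rho), corr$rho,
                     check.names = FALSE)
    utils::write.table(df, rho_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, rho_path)
  }
  if (!is.null(edges_path) && !is.null(edges)) {
    utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, edges_path)
  }
  invisible(written)
}
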