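#' Convert an abundance table to relative abundances
#'
#' Abundance tables are oriented samples x taxa throughout the package.
#' Each row (sample) is divided by its total so rows sum to one. Tables that
#' are already relative pass through unchanged up to numerical noise
#' (the operation is idempotent).
#'
#' @param table Numeric matrix or data frame, samples in rows, taxa in
#'   columns, non-negative entries.
#' @return Matrix of relative abundances with the same dimnames.
#' @export
to_relative <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("abundance table must be numeric", call. = FALSE)
  if (any(m < 0)) stop("abundance table has negative entries", call. = FALSE)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    bad <- rownames(m)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("zero-total sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(m, 1, totals, "/")
}

#' Inclusion filter for co-occurrence network construction
#'
#' Keeps taxa whose relative abundance exceeds `min_rel_abund` in at least
#' `min_occurrence` samples of the table. The defaults encode the usual
#' network inclusion rule for genus-level digester communities: above 0.1%
#' relative abundance in more than two (i.e. at least three) samples.
#' Because networks are built per sample group, the filter is meant to be
#' applied to one group's samples at a time.
#'
#' @param table Samples x taxa table of relative abundances (rows summing
#'   to 1; counts are converted via [to_relative()] first).
#' @param min_rel_abund Relative-abundance threshold (default 0.001 = 0.1%).
#' @param min_occurrence Minimum number of samples in which the threshold
#'   must be exceeded (default 3).
#' Abundances in the returned table stay relative to the \emph{full}
#' community (rows of a filtered table sum to slightly less than 1), so the
#' filter is exactly idempotent and thresholds keep their community-wide
#' meaning.
#'
#' @return The filtered relative-abundance matrix, with attribute
#'   `"dropped"` listing the taxa removed.
#' @export
network_filter <- function(table, min_rel_abund = 0.001, min_occurrence = 3) {
  m <- as.matrix(table)
  totals <- rowSums(m)
  rel <- if (all(totals <= 1 + 1e-6)) m else to_relative(m)
  if (nrow(rel) < 4L)
    stop("network_filter: fewer than 4 samples; correlations over so few ",
         "samples are not meaningful", call. = FALSE)
  hits <- colSums(rel > min_rel_abund)
  keep <- hits >= min_occurrence
  out <- rel[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(rel)[!keep]
  out
}

#' Alpha diversity per sample
#'
#' Shannon diversity \eqn{H = -\sum p \ln p} (natural log, zero-abundance
#' taxa excluded), genus richness (count of taxa present), and Pielou
#' evenness \eqn{H / \ln(richness)}. A single-taxon sample has H = 0 and
#' evenness defined as 0.
#'
#' @param table Samples x taxa abundance table (counts or relative).
#' @return Data frame with columns `sample`, `shannon`, `richness`,
#'   `evenness`.
#' @export
alpha_diversity <- function(table) {
  rel <- to_relative(table)
  shannon <- vegan::diversity(rel, index = "shannon")
  richness <- rowSums(rel > 0)
  evenness <- ifelse(richness > 1, shannon / log(richness), 0)
  data.frame(sample = if (is.null(rownames(rel))) as.character(seq_len(nrow(rel)))
             else rownames(rel),
             shannon = unname(shannon),
             richness = unname(richness),
             evenness = unname(evenness),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}; 0 for identical
#' samples, 1 for samples with disjoint taxon support.
#'
#' @param table Samples x taxa abundance table.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("negative abundances", call. = FALSE)
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Ordinates a distance matrix by eigen-decomposition of the double-centred
#' Gower matrix. Axes are ordered by eigenvalue; axes with negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported but dropped from the returned coordinates.
#'
#' @param d A `dist` object or square symmetric matrix of dissimilarities.
#' @param k Maximum number of axes to return (default all positive axes).
#' @return List with `points` (samples x axes coordinate matrix), `eig`
#'   (all eigenvalues), `prop_explained` (share of the positive eigenvalue
#'   mass per returned axis), and `n_negative_eig`.
#' @export
pcoa <- function(d, k = NULL) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
      stop("distance matrix must be square and symmetric", call. = FALSE)
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- sqrt(.Machine$double.eps) * max(abs(eig))
  pos <- which(eig > tol)
  if (is.null(k)) k <- length(pos)
  k <- min(k, length(pos), ncol(fit$points))
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("PCoA", seq_len(k))
  list(points = pts,
       eig = eig,
       prop_explained = eig[seq_len(k)] / sum(eig[pos]),
       n_negative_eig = sum(eig < -tol))
}

#' Deterministic steady-state subsampling of an over-represented group
#'
#' When one group contributes many more samples than the others, its network
#' would be built over a different effective sample size. This helper
#' reduces a group to at most `max_per_group` samples, preferring samples
#' flagged as steady state, then later stages, breaking remaining ties
#' lexically by sample id so repeated runs select identically.
#'
#' @param table Samples x taxa abundance table.
#' @param metadata Data frame with columns `sample`, and optionally
#'   `steady_state` (logical) and `stage` (numeric, larger = later).
#' @param max_per_group Maximum samples retained (default 8).
#' @return The subsetted table, with attribute `"dropped"` naming removed
#'   samples.
#' @export
subsample_steady_state <- function(table, metadata, max_per_group = 8) {
  m <- as.matrix(table)
  if (is.null(rownames(m))) stop("table needs sample rownames", call. = FALSE)
  if (!"sample" %in% names(metadata))
    stop("metadata needs a 'sample' column", call. = FALSE)
  meta <- metadata[match(rownames(m), metadata$sample), , drop = FALSE]
  if (nrow(m) <= max_per_group) {
    attr(m, "dropped") <- character(0)
    return(m)
  }
  steady <- if ("steady_state" %in% names(meta)) as.logical(meta$steady_state)
            else rep(TRUE, nrow(m))
  stage <- if ("stage" %in% names(meta)) as.numeric(meta$stage)
           else rep(0, nrow(m))
  ord <- order(-steady, -stage, rownames(m))
  keep <- sort(ord[seq_len(max_per_group)])
  out <- m[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(m)[-keep]
  out
}

#' Read an abundance table from TSV
#'
#' @param path Tab-separated file with taxon/sample labels in the first
#'   column and remaining columns numeric.
#' @param orientation `"samples_x_taxa"` (default) or `"taxa_x_samples"`
#'   (transposed on read).
#' @return Numeric matrix, samples in rows.
#' @export
read_abundance_tsv <- function(path,
                               orientation = c("samples_x_taxa",
                                               "taxa_x_samples")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric abundance table", call. = FALSE)
  if (orientation == "taxa_x_samples") m <- t(m)
  m
}

#' Read an abundance table from a BIOM file
#'
#' Thin wrapper over the biomformat package, returning the package's
#' samples x taxa matrix orientation.
#'
#' @param path Path to a BIOM (JSON or HDF5) file.
#' @return Numeric matrix, samples in rows, taxa in columns.
#' @export
read_abundance_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
  t(m)
}

#' Write an abundance table as TSV
#'
#' @param table Samples x taxa matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(table, path) {
  df <- data.frame(sample = rownames(table), as.data.frame(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
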