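#' Correlate network properties with reactor parameters across groups
#'
#' For every (network property, reactor parameter) pair, computes the
#' correlation over groups with a two-sided t-test on n - 2 degrees of
#' freedom and flags significance at `alpha`. Pearson correlation is the
#' default, matching the usual presentation of such matrices; Spearman is
#' available because with as few as five groups Pearson p-values are
#' fragile — a warning is emitted whenever fewer than six paired groups
#' enter the test.
#'
#' @param panels Data frame of group-level network properties (one row per
#'   group) — typically rbind-ed [topology_panel()] rows. Must contain a
#'   `group` column.
#' @param params Data frame of group-level reactor metrics with a `group`
#'   column — typically [derive_metrics()] output.
#' @param alpha Significance level for the flag (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param properties,parameters Optional column selections; defaults to all
#'   numeric columns of each table.
#' @param adjust_p If `TRUE`, Benjamini-Hochberg adjust across the grid
#'   (off by default, matching the starred-matrix convention).
#' @return Data frame of class `linkage_result`: `property`, `parameter`,
#'   `r`, `p`, `n`, `significant`. Pairs with zero variance are reported
#'   with `NA` r and p.
#' @export
linkage_matrix <- function(panels, params, alpha = 0.05,
                           method = c("pearson", "spearman"),
                           properties = NULL, parameters = NULL,
                           adjust_p = FALSE) {
  method <- match.arg(method)
  if (!"group" %in% names(panels) || !"group" %in% names(params))
    stop("both tables need a 'group' column", call. = FALSE)
  shared <- intersect(panels$group, params$group)
  if (length(shared) < 3)
    stop("need at least 3 groups with both network properties and ",
         "reactor parameters", call. = FALSE)
  if (length(shared) < 6)
    warning("only ", length(shared), " groups: correlation p-values over ",
            "so few points are fragile; interpret with care")
  pa <- panels[match(shared, panels$group), , drop = FALSE]
  pr <- params[match(shared, params$group), , drop = FALSE]
  num_cols <- function(df) names(df)[vapply(df, is.numeric, logical(1))]
  if (is.null(properties)) properties <- num_cols(pa)
  if (is.null(parameters)) parameters <- num_cols(pr)

  grid <- expand.grid(property = properties, parameter = parameters,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- pa[[grid$property[i]]]
    y <- pr[[grid$parameter[i]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(c(r = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = method))
    c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  res <- do.call(rbind, res)
  out <- data.frame(grid, r = res[, "r"], p = res[, "p"],
                    n = as.integer(res[, "n"]),
                    stringsAsFactors = FALSE)
  if (adjust_p) out$p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  class(out) <- c("linkage_result", class(out))
  out
}

#' Sample-size confounding check
#'
#' Correlates each network property with the number of samples behind each
#' group's network (and with network order, which tracks it), flagging any
#' association significant at `alpha` as a potential confounder. When the
#' per-group sample counts differ, network size is expected to respond;
#' other properties should not.
#'
#' @param panels Group-level property rows (with `group` column).
#' @param sample_counts Named vector (or data frame with `group` and `n`)
#'   of samples per group.
#' @param alpha Flagging level (default 0.05).
#' @return `linkage_result` grid of properties vs `sample_count`, plus a
#'   `flagged` attribute listing properties whose correlation with sample
#'   count is significant.
#' @export
size_confound_check <- function(panels, sample_counts, alpha = 0.05) {
  if (is.data.frame(sample_counts))
    sample_counts <- stats::setNames(sample_counts$n, sample_counts$group)
  counts <- data.frame(group = names(sample_counts),
                       sample_count = as.numeric(sample_counts),
                       stringsAsFactors = FALSE)
  out <- suppressWarnings(
    linkage_matrix(panels, counts, alpha = alpha,
                   parameters = "sample_count"))
  attr(out, "flagged") <- out$property[out$significant]
  out
}

#' Write a linkage grid as tidy and matrix-form TSV
#'
#' @param linkage A [linkage_matrix()] result.
#' @param tidy_path,matrix_path Output paths (`NULL` skips).
#' @return Invisibly, the paths written.
#' @export
write_linkage <- function(linkage, tidy_path = NULL, matrix_path = NULL) {
  written <- character(0)
  if (!is.null(tidy_path)) {
    utils::write.table(linkage, tidy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tidy_path)
  }
  if (!is.null(matrix_path)) {
    wide <- stats::reshape(
      as.data.frame(linkage)[, c("property", "parameter", "r")],
      idvar = "property", timevar = "parameter", direction = "wide")
    names(wide) <- sub("^r\\.", "", names(wide))
    utils::write.table(wide, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, matrix_path)
  }
  invisible(written)
}
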