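#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()]:
#' input locations, thresholds for every stage, seeds, replicate counts and
#' the output directory. A configuration can also be read from a YAML file
#' with the same field names via [read_pipeline_config()].
#'
#' @param abundance Path to the abundance TSV (samples x taxa), or `NULL`
#'   to simulate input with [simulate_community()].
#' @param metadata Path to the sample metadata TSV (`sample`, `group`,
#'   optionally `reactor`, `stage`, `steady_state`); `NULL` with simulated
#'   input.
#' @param chemistry Path to a reactor chemistry TSV with a `group` column,
#'   or `NULL` (simulated along with the community when `abundance` is
#'   `NULL`; otherwise the linkage stage is skipped).
#' @param out_dir Output directory.
#' @param min_rel_abund,min_occurrence Inclusion filter thresholds
#'   (defaults 0.001 and 3), see [network_filter()].
#' @param r_min,p_max Edge thresholds (defaults 0.6 and 0.01), see
#'   [select_edges()].
#' @param p_method p-value method for [spearman_matrix()].
#' @param z_threshold,p_threshold Role thresholds, see [classify_roles()].
#' @param alpha Linkage significance level.
#' @param max_per_group Steady-state subsampling cap (default 8).
#' @param n_reps Random-baseline replicates (default 100).
#' @param seed Integer seed used for every stochastic step (and the
#'   simulator when no input paths are given).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(abundance = NULL, metadata = NULL,
                            chemistry = NULL, out_dir = "digestnet_out",
                            min_rel_abund = 0.001, min_occurrence = 3,
                            r_min = 0.6, p_max = 0.01, p_method = "t",
                            z_threshold = 2.5, p_threshold = 0.62,
                            alpha = 0.05, max_per_group = 8,
                            n_reps = 100, seed = 1L) {
  cfg <- list(abundance = abundance, metadata = metadata,
              chemistry = chemistry, out_dir = out_dir,
              min_rel_abund = as.numeric(min_rel_abund),
              min_occurrence = as.integer(min_occurrence),
              r_min = as.numeric(r_min), p_max = as.numeric(p_max),
              p_method = as.character(p_method),
              z_threshold = as.numeric(z_threshold),
              p_threshold = as.numeric(p_threshold),
              alpha = as.numeric(alpha),
              max_per_group = as.integer(max_per_group),
              n_reps = as.integer(n_reps), seed = as.integer(seed))
  stopifnot(cfg$min_rel_abund >= 0, cfg$min_rel_abund < 1,
            cfg$min_occurrence >= 1,
            cfg$r_min >= 0, cfg$r_min <= 1,
            cfg$p_max > 0, cfg$p_max <= 1,
            cfg$alpha > 0, cfg$alpha <= 1,
            cfg$n_reps >= 1, cfg$max_per_group >= 4)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full co-occurrence analysis pipeline
#'
#' Executes, per sample group: inclusion filtering, Spearman correlation,
#' edge selection, network construction, topology panel with random
#' baseline, Zi-Pi role classification and hub ranking; then correlates
#' the per-group topology panels with derived reactor metrics (when
#' chemistry is available) and runs the sample-size confounding check.
#' Every output is a TSV (GraphML for graphs); a manifest with the MD5
#' checksum of each artifact, the configuration echo and the package
#' version is written last, so identical config + seed reruns produce
#' identical manifests.
#'
#' Groups whose filtered table, edge list or graph is degenerate (too few
#' samples, no significant edges) are skipped with a logged warning rather
#' than aborting the run.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @return Invisibly, a list with `manifest` (data frame of artifacts and
#'   checksums), `panels`, `linkage`, and per-group results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  if (is.null(config$abundance)) {
    note("no input abundance table: simulating (seed ", config$seed, ")")
    sim_cfg <- sim_config(seed = config$seed)
    sim <- simulate_community(sim_cfg)
    counts <- sim$counts
    meta <- sim$metadata
    chem <- simulate_reactor_params(sim_cfg, sim$truth)
    write_simulation(sim, file.path(config$out_dir, "simulation"),
                     chem = chem)
  } else {
    for (f in c(config$abundance, config$metadata))
      if (!is.null(f) && !file.exists(f))
        stop("missing input file: ", f, call. = FALSE)
    counts <- read_abundance_tsv(config$abundance)
    meta <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(meta)))
      stop("metadata needs 'sample' and 'group' columns", call. = FALSE)
    chem <- NULL
    if (!is.null(config$chemistry)) {
      if (!file.exists(config$chemistry))
        stop("missing input file: ", config$chemistry, call. = FALSE)
      chem <- utils::read.delim(config$chemistry, stringsAsFactors = FALSE)
    }
  }

  groups <- unique(meta$group)
  panels <- list()
  group_results <- list()
  sample_counts <- integer(0)
  for (g in groups) {
    tab <- counts[meta$sample[meta$group == g], , drop = FALSE]
    tab <- subsample_steady_state(tab, meta,
                                  max_per_group = config$max_per_group)
    if (nrow(tab) < 4) {
      note("group ", g, ": fewer than 4 samples, skipped")
      next
    }
    filt <- tryCatch(
      network_filter(to_relative(tab), config$min_rel_abund,
                     config$min_occurrence),
      error = function(e) NULL)
    if (is.null(filt) || ncol(filt) < 2) {
      note("group ", g, ": no taxa pass the inclusion filter, skipped")
      next
    }
    if (length(attr(filt, "dropped")))
      note("group ", g, ": dropped ", length(attr(filt, "dropped")),
           " taxa below ", config$min_rel_abund, " in < ",
           config$min_occurrence, " samples")
    corr <- spearman_matrix(filt, p_method = config$p_method)
    edges <- select_edges(corr, r_min = config$r_min,
                          p_max = config$p_max)
    if (nrow(edges) == 0) {
      note("group ", g, ": no edges at |rho| > ", config$r_min,
           ", p < ", config$p_max, "; skipped")
      next
    }
    net <- build_network(edges, node_abundance = colMeans(filt),
                         group = g)
    panel <- topology_panel(net, n_reps = config$n_reps,
                            seed = config$seed)
    nodes <- zi_pi(net, attr(panel, "membership"))
    nodes <- classify_roles(nodes, config$z_threshold, config$p_threshold)
    hubs <- rank_hubs(nodes)

    prefix <- file.path(config$out_dir, paste0("network_", g))
    write_correlation(corr, edges,
                      edges_path = paste0(prefix, "_edges.tsv"))
    write_network(net, graphml_path = paste0(prefix, ".graphml"))
    write_node_table(nodes, paste0(prefix, "_nodes.tsv"))
    comp <- attr(average_path_length(net), "components")
    if (length(comp) > 1)
      note("group ", g, ": graph has ", length(comp),
           " components (sizes ", paste(comp, collapse = ","), ")")
    panels[[g]] <- panel
    sample_counts[g] <- nrow(tab)
    group_results[[g]] <- list(panel = panel, nodes = nodes, hubs = hubs,
                               n_samples = nrow(tab))
  }
  if (!length(panels))
    stop("no group produced a network", call. = FALSE)
  panel_df <- do.call(rbind, panels)
  rownames(panel_df) <- NULL
  utils::write.table(panel_df,
                     file.path(config$out_dir, "topology_panels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  linkage <- NULL
  if (!is.null(chem)) {
    metrics <- derive_metrics(chem)
    write_derived_metrics(metrics,
                          file.path(config$out_dir, "derived_metrics.tsv"))
    if (length(panels) >= 3) {
      linkage <- suppressWarnings(
        linkage_matrix(panel_df, metrics, alpha = config$alpha))
      write_linkage(linkage,
                    tidy_path = file.path(config$out_dir, "linkage.tsv"))
      if (length(panels) < 6)
        note("linkage computed over only ", length(panels),
             " groups: p-values are fragile")
    }
  }
  confound <- size_confound_check(panel_df, sample_counts,
                                  alpha = config$alpha)
  write_linkage(confound,
                tidy_path = file.path(config$out_dir,
                                      "size_confounding.tsv"))
  if (length(attr(confound, "flagged")))
    note("sample-count confounding flagged for: ",
         paste(attr(confound, "flagged"), collapse = ", "))

  writeLines(log_lines, file.path(config$out_dir, "pipeline_log.txt"))
  manifest <- .write_manifest(config)
  invisible(list(manifest = manifest, panels = panel_df,
                 linkage = linkage, confound = confound,
                 groups = group_results))
}

# manifest: every artifact with its checksum, plus a config echo; written
# with fixed ordering so identical runs are byte-identical
.write_manifest <- function(config) {
  files <- sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                        "manifest.tsv"))
  paths <- file.path(config$out_dir, files)
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  cfg_echo <- unlist(lapply(unclass(config), function(x)
    if (is.null(x)) "NULL" else paste(x, collapse = ",")))
  header <- c("# digestnet manifest",
              paste0("# package_version: ",
                     as.character(utils::packageVersion("digestnet"))),
              paste0("# config_", names(cfg_echo), ": ", cfg_echo))
  con <- file(file.path(config$out_dir, "manifest.tsv"), "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(manifest, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest
}
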