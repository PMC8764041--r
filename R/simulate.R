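#' Configuration for the synthetic digester-community simulator
#'
#' Builds and validates the configuration of the compositional community
#' simulator. The defaults emulate the sampling design the package's
#' analyses are aimed at: 52 sludge samples from 12 reactors falling into
#' five community groups (ambient, mesophilic low-solid-substrate,
#' mesophilic, mesophilic co-digestion, thermophilic), genus-level tables
#' with a large bacterial block and a small, more dominance-skewed archaeal
#' block, and per-group planted module structure.
#'
#' Taxa within a module share a latent factor per sample
#' (log-abundance = base + loading x factor + noise), so module mates are
#' strongly rank-correlated while taxa in different modules are
#' conditionally independent. `module_strength` sets the loading magnitude
#' per group; it differs across groups by default so that network density
#' and clustering vary between groups the way they do between real
#' digester regimes. A small fraction of taxa load negatively on their
#' module's factor, producing the negative edges real co-occurrence
#' networks contain.
#'
#' @param n_groups Number of community groups (default 5).
#' @param group_names Labels, length `n_groups`.
#' @param samples_per_group Samples per group (default `c(20, 6, 13, 5, 8)`
#'   — 52 in total; the over-sampled first group is meant to be reduced to
#'   8 steady-state samples before network analysis).
#' @param reactors_per_group Reactors per group (default `c(5, 2, 2, 1, 2)`
#'   = 12).
#' @param n_taxa_bacteria,n_taxa_archaea Taxon counts (defaults 150 / 15).
#' @param n_modules Planted modules per group (default 4).
#' @param module_strength Latent-factor loading per group, recycled to
#'   `n_groups` (default `c(2.0, 1.6, 1.8, 2.2, 2.4)`, chosen so
#'   within-module log-abundance correlations sit near 0.97-0.99 and vary
#'   by group, while keeping single-module compositional dominance in
#'   check).
#' @param noise_sd Taxon-level log-scale noise (default 0.25).
#' @param neg_loading_frac Fraction of taxa with negative loadings
#'   (default 0.08).
#' @param zero_inflation_prob Maximum dropout probability (default 0.05);
#'   the realised per-observation dropout decays exponentially with the
#'   taxon's proportion in that sample, so only genera near the detection
#'   limit are affected appreciably.
#' @param sequencing_depth Reads per sample (default 50000).
#' @param effect_size Linear dependence of group-level hydrolysis
#'   efficiency on `module_strength` used by [simulate_reactor_params()]
#'   (default 0.25 per unit loading; 0 removes the dependence).
#' @param seed Integer seed; the seed fully determines all output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 5,
                       group_names = c("ambient", "meso_low_solid",
                                       "mesophilic", "meso_codigestion",
                                       "thermophilic"),
                       samples_per_group = c(20, 6, 13, 5, 8),
                       reactors_per_group = c(5, 2, 2, 1, 2),
                       n_taxa_bacteria = 150,
                       n_taxa_archaea = 15,
                       n_modules = 4,
                       module_strength = c(2.0, 1.6, 1.8, 2.2, 2.4),
                       noise_sd = 0.25,
                       neg_loading_frac = 0.08,
                       zero_inflation_prob = 0.05,
                       sequencing_depth = 50000,
                       effect_size = 0.25,
                       seed = 1L) {
  cfg <- list(n_groups = as.integer(n_groups),
              group_names = rep_len(as.character(group_names), n_groups),
              samples_per_group = rep_len(as.integer(samples_per_group),
                                          n_groups),
              reactors_per_group = rep_len(as.integer(reactors_per_group),
                                           n_groups),
              n_taxa_bacteria = as.integer(n_taxa_bacteria),
              n_taxa_archaea = as.integer(n_taxa_archaea),
              n_modules = as.integer(n_modules),
              module_strength = rep_len(as.numeric(module_strength),
                                        n_groups),
              noise_sd = as.numeric(noise_sd),
              neg_loading_frac = as.numeric(neg_loading_frac),
              zero_inflation_prob = as.numeric(zero_inflation_prob),
              sequencing_depth = as.integer(sequencing_depth),
              effect_size = as.numeric(effect_size),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_groups >= 1, all(samples_per_group >= 1),
              all(reactors_per_group >= 1),
              n_taxa_bacteria >= n_modules, n_taxa_archaea >= 0,
              n_modules >= 1, all(module_strength >= 0), noise_sd >= 0,
              neg_loading_frac >= 0, neg_loading_frac <= 1,
              zero_inflation_prob >= 0, zero_inflation_prob <= 1,
              sequencing_depth >= 1)
  })
  if (anyDuplicated(cfg$group_names))
    stop("group names must be unique", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genus-level community table with planted module structure
#'
#' Generates counts for every sample of every group under a log-normal
#' latent-factor compositional model: each group has its own random
#' assignment of taxa to `n_modules` modules; per sample, each module draws
#' one standard-normal factor; a taxon's log-abundance is its baseline plus
#' (signed loading x its module's factor) plus Gaussian noise; per-sample
#' abundances are closed to proportions and resampled multinomially at the
#' configured sequencing depth, after which zero-inflation independently
#' knocks observed counts to zero. This is a test harness with known ground
#' truth, not a mechanistic model of digester ecology.
#'
#' @param cfg A [sim_config()].
#' @return List of class `ad_simulation`:
#'   \describe{
#'     \item{counts}{samples x taxa integer matrix.}
#'     \item{metadata}{data frame: `sample`, `group`, `reactor`, `stage`,
#'       `steady_state`.}
#'     \item{truth}{list with `modules` (taxa x groups module assignment),
#'       `loading_sign` (taxa x groups, +1/-1), `module_strength`,
#'       `taxonomy` (taxon domain), and the full `config`.}
#'   }
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$sequencing_depth < 1000)
    warning("sequencing depth below 1000 cannot represent taxa near the ",
            "0.1% inclusion threshold")
  set.seed(cfg$seed)
  n_taxa <- cfg$n_taxa_bacteria + cfg$n_taxa_archaea
  taxa <- c(sprintf("g__Bact%03d", seq_len(cfg$n_taxa_bacteria)),
            sprintf("g__Arch%02d", seq_len(cfg$n_taxa_archaea)))
  domain <- rep(c("Bacteria", "Archaea"),
                c(cfg$n_taxa_bacteria, cfg$n_taxa_archaea))

  # baseline log-abundances; archaea: fewer taxa, stronger dominance skew
  base <- c(stats::rnorm(cfg$n_taxa_bacteria, 0, 1.2),
            stats::rnorm(cfg$n_taxa_archaea, -1, 2.0))
  if (cfg$n_taxa_archaea > 0) {
    dom <- cfg$n_taxa_bacteria + sample.int(cfg$n_taxa_archaea, 1)
    base[dom] <- base[dom] + 3
  }

  modules <- matrix(0L, n_taxa, cfg$n_groups,
                    dimnames = list(taxa, cfg$group_names))
  signs <- matrix(1L, n_taxa, cfg$n_groups,
                  dimnames = list(taxa, cfg$group_names))
  for (gi in seq_len(cfg$n_groups)) {
    modules[, gi] <- sample(rep_len(seq_len(cfg$n_modules), n_taxa))
    neg <- sample.int(n_taxa, round(cfg$neg_loading_frac * n_taxa))
    signs[neg, gi] <- -1L
  }

  meta <- .sim_metadata(cfg)
  counts <- matrix(0L, nrow(meta), n_taxa,
                   dimnames = list(meta$sample, taxa))
  for (s in seq_len(nrow(meta))) {
    gi <- match(meta$group[s], cfg$group_names)
    f <- stats::rnorm(cfg$n_modules)
    logx <- base +
      signs[, gi] * cfg$module_strength[gi] * f[modules[, gi]] +
      stats::rnorm(n_taxa, 0, cfg$noise_sd)
    p <- exp(logx - max(logx))
    p <- p / sum(p)
    cts <- stats::rmultinom(1, cfg$sequencing_depth, p)[, 1]
    if (cfg$zero_inflation_prob > 0) {
      # dropout concentrates on taxa near the detection limit: a genus at
      # several percent of a sample does not vanish from it, one at ~0.1%
      # occasionally does
      p_drop <- cfg$zero_inflation_prob * exp(-p / 0.002)
      drop <- stats::runif(n_taxa) < p_drop
      cts[drop] <- 0L
    }
    counts[s, ] <- cts
  }

  structure(list(counts = counts,
                 metadata = meta,
                 truth = list(modules = modules,
                              loading_sign = signs,
                              module_strength = stats::setNames(
                                cfg$module_strength, cfg$group_names),
                              taxonomy = stats::setNames(domain, taxa),
                              config = cfg)),
            class = "ad_simulation")
}

# sample sheet: reactors, stages, steady-state flags. The first group is
# over-sampled on purpose; its last stages per reactor are flagged steady so
# that steady-state subsampling reduces it to 8 samples.
.sim_metadata <- function(cfg) {
  rows <- list()
  for (gi in seq_len(cfg$n_groups)) {
    g <- cfg$group_names[gi]
    n_s <- cfg$samples_per_group[gi]
    n_r <- cfg$reactors_per_group[gi]
    reactor <- sprintf("%s_R%d", g, rep_len(seq_len(n_r), n_s))
    stage <- stats::ave(seq_len(n_s), reactor, FUN = seq_along)
    steady <- rep(TRUE, n_s)
    if (n_s > 8) {
      # flag the 8 latest-stage samples (ties broken by reactor order)
      ord <- order(-stage, reactor)
      steady <- rep(FALSE, n_s)
      steady[ord[1:8]] <- TRUE
    }
    rows[[gi]] <- data.frame(
      sample = sprintf("%s_s%02d", g, seq_len(n_s)),
      group = g, reactor = reactor, stage = stage, steady_state = steady,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate group-level reactor chemistry tied to network strength
#'
#' Generates one row of reactor chemistry per group, in the value ranges
#' typical of blackwater digesters (influent COD from ~1 to ~33 g/L, TAN up
#' to ~1.4 g-N/L, SMA 0.1-0.45 gCOD/gVSS/d), with the group's hydrolysis
#' efficiency depending linearly on its planted `module_strength` with
#' coefficient `cfg$effect_size`. With a positive coefficient, groups whose
#' communities co-vary more tightly also hydrolyse better, so downstream
#' topology-parameter correlations have a known expected sign; with
#' `effect_size = 0` the expected correlation is zero.
#'
#' @param cfg A [sim_config()].
#' @param truth The `truth` element of [simulate_community()] output (used
#'   for the per-group module strengths).
#' @return Data frame, one row per group, with the measured-chemistry
#'   columns consumed by [derive_metrics()] plus `SMA_total`, `SMA_obs` and
#'   `K_H`.
#' @export
simulate_reactor_params <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  lam <- truth$module_strength
  set.seed(cfg$seed + 1000L)
  n_g <- cfg$n_groups
  temperature <- rep_len(c(22, 35, 35, 35, 52), n_g)
  TAN <- rep_len(c(200, 961, 650, 1319, 1217), n_g) *
    stats::runif(n_g, 0.95, 1.05)
  pH <- rep_len(c(7.0, 8.2, 7.7, 7.3, 7.0), n_g) +
    stats::rnorm(n_g, 0, 0.05)
  tCOD_inf <- rep_len(c(1.0, 3.7, 5.5, 32.5, 30.0), n_g) *
    stats::runif(n_g, 0.9, 1.1)

  hyd <- 0.25 + cfg$effect_size * (lam - mean(lam)) +
    stats::rnorm(n_g, 0, 0.03)
  hyd <- pmin(pmax(hyd, 0.05), 0.9)
  meth <- hyd * stats::runif(n_g, 0.85, 0.98)

  pCOD_ratio <- stats::runif(n_g, 0.4, 0.8)
  sCOD_inf <- tCOD_inf * (1 - pCOD_ratio)
  # choose COD removal small enough that the implied effluent soluble COD
  # stays below effluent total COD
  removed <- 0.8 * (tCOD_inf - sCOD_inf) / (1 + hyd - meth)
  tCOD_eff <- tCOD_inf - removed
  COD_CH4 <- meth * removed
  sCOD_eff <- sCOD_inf + (hyd - meth) * removed

  SMA_total <- stats::runif(n_g, 0.1, 0.45)
  SMA_obs <- SMA_total * stats::runif(n_g, 0.3, 0.9)
  K_H <- stats::runif(n_g, 0.05, 0.5)

  data.frame(group = cfg$group_names,
             temperature_C = temperature,
             TAN = TAN, pH = pH,
             tCOD_inf = tCOD_inf, tCOD_eff = tCOD_eff,
             sCOD_inf = sCOD_inf, sCOD_eff = sCOD_eff,
             COD_CH4 = COD_CH4,
             SMA_total = SMA_total, SMA_obs = SMA_obs, K_H = K_H,
             stringsAsFactors = FALSE)
}

#' Write a simulation to disk
#'
#' Writes the counts table, sample metadata and reactor chemistry as TSV
#' and the ground truth (module assignments, loading signs, config) as
#' JSON.
#'
#' @param sim An `ad_simulation` from [simulate_community()].
#' @param dir Output directory (created if needed).
#' @param chem Optional reactor table from [simulate_reactor_params()].
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir, chem = NULL) {
  stopifnot(inherits(sim, "ad_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_abundance_tsv(sim$counts, paths["counts"])
  utils::write.table(sim$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(chem)) {
    paths <- c(paths, chem = file.path(dir, "reactor_chemistry.tsv"))
    utils::write.table(chem, paths["chem"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
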