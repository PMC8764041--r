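# digestnet

Co-occurrence network analysis of anaerobic digestion (AD) microbiomes:
from reactor chemistry and genus-level abundance tables to per-group
correlation networks, and back to the question engineers actually care
about — *which network properties track reactor performance?*

AD performance rests on cooperation between microbial guilds (hydrolysers,
acidogens, acetogens, methanogens). `digestnet` quantifies that
cooperation as graph structure and links it to process metrics:

* **Derived reactor metrics** — free ammonia
  FA = 1.214·TAN·(1 + 10^(−pH)/10^(−(0.09018 + 2729.92/T)))^(−1)
  (T in Kelvin), hydrolysis efficiency
  (sCOD_eff − sCOD_inf + COD_CH₄)/(tCOD_inf − tCOD_eff), methanogenesis
  efficiency COD_CH₄/(tCOD_inf − tCOD_eff), first-order hydrolysis rate
  constant K_H from batch series, particulate COD ratio, and the
  imbalance indices D_efficiency and D_rate.
* **Community preparation** — relative abundance, the network inclusion
  filter (> 0.1% relative abundance in ≥ 3 samples of the group), Shannon
  diversity / richness / evenness, Bray–Curtis distance and PCoA,
  deterministic steady-state subsampling of over-represented groups.
* **Networks** — all-pairs Spearman correlation (t, exact-permutation and
  Monte-Carlo p-values), edges at |ρ| > 0.6 and p < 0.01 with sign,
  topology panels (clustering coefficient, modularity, positive ratio,
  average path length, degree and betweenness centralities, order, size)
  against seeded Erdős–Rényi G(n,m) baselines, and discrete power-law
  degree fits with bootstrap goodness of fit.
* **Ecological roles** — within-module connectivity Z_i and among-module
  participation P_i = 1 − Σ_s (k_is/k_i)², quadrant classification
  (peripherals / module hubs / connectors / network hubs), hub and
  gatekeeper rankings, and the abundance-vs-centrality test that flags
  low-abundance keystone candidates.
* **Linkage** — Pearson (or Spearman) correlation of group-level network
  properties with reactor parameters, with a sample-size confounding
  check.
* **Synthetic data** — a seeded compositional simulator with planted
  module structure (52 samples, 12 reactors, 5 groups by default) so the
  whole pipeline is testable without sequence data.

## Worked example

```r
library(digestnet)

## free ammonia at mesophilic regular-substrate conditions
free_ammonia(TAN = 93, pH = 7.5, temperature_C = 35)
#> [1] 3.876  # mg-N/L, i.e. ~4% of TAN is un-ionised at pH 7.5, 35 C

## simulate the default five-group design and derive reactor metrics
cfg  <- sim_config(seed = 1)
sim  <- simulate_community(cfg)
chem <- simulate_reactor_params(cfg, sim$truth)
derive_metrics(chem)[, c("group", "hydrolysis_eff", "pCOD_ratio")]
#>              group hydrolysis_eff pCOD_ratio
#>          ambient            0.259      0.450
#>   meso_low_solid            0.199      0.436
#>       mesophilic            0.181      0.698
#> meso_codigestion            0.314      0.684
#>     thermophilic            0.393      0.435

## build one group's co-occurrence network
idx   <- sim$metadata$group == "mesophilic"
filt  <- network_filter(to_relative(sim$counts[idx, ]))   # 150 of 165 taxa
edges <- select_edges(spearman_matrix(filt))              # |rho|>0.6, p<0.01
net   <- build_network(edges, node_abundance = colMeans(filt),
                       group = "mesophilic")
panel <- topology_panel(net, n_reps = 100, seed = 1)
panel[, c("clustering_coefficient", "random_clustering_coefficient",
          "modularity", "positive_ratio", "average_path_length")]
#>   clustering_coefficient random_clustering_coefficient modularity
#> 1                  0.981                         0.232      0.743
#>   positive_ratio average_path_length
#> 1          0.914                1.67
```

The real network's clustering coefficient (0.98) sits far above its
random-graph baseline (0.23): taxa co-occur in tight, triangle-rich
clusters rather than at random — here, the modules planted by the
simulator. Node-level roles then come from the partition:

```r
nodes <- classify_roles(zi_pi(net, attr(panel, "membership")))
rank_hubs(nodes, top_n = 5)$by_degree[, c("taxon", "normalized_degree",
                                          "abundance")]
#>        taxon normalized_degree abundance
#> 1 g__Bact119              0.28    0.0061
#> 2  g__Arch01              0.26    0.0028
#> 3  g__Arch07              0.26    0.0106
#> 4 g__Bact006              0.26    0.0017
#> 5 g__Bact020              0.26    0.0102
```

Note the top hubs include genera at 0.2–0.6% relative abundance:
centrality is not dominance.

The whole analysis — filter, correlate, build, panel, roles, linkage,
manifest — runs as one deterministic pipeline:

```r
run_pipeline(pipeline_config(out_dir = "out", seed = 1))
```

or from a shell via `inst/scripts/digestnet_cli.R`
(`simulate | metrics | network | pipeline` subcommands).

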