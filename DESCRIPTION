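Package: digestnet
Title: Co-Occurrence Network Analysis of Anaerobic Digestion Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links anaerobic digestion reactor performance to the topology of
    microbial co-occurrence networks. Computes derived reactor metrics (free
    ammonia, hydrolysis and methanogenesis efficiency, first-order hydrolysis
    rate constant, relative differential efficiency and rate), prepares
    genus-level abundance tables (relative abundance, inclusion filters,
    alpha diversity, Bray-Curtis ordination), builds per-group Spearman
    co-occurrence networks with significance thresholds, summarises network
    topology against Erdos-Renyi baselines and power-law degree fits,
    classifies taxa into ecological roles by within- and among-module
    connectivity (Zi-Pi), and correlates network properties with reactor
    parameters. Includes a compositional community simulator with planted
    module structure so every stage is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    vegan,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    biomformat
Config/testthat/edition: 3
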