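---
title: "Linking digester performance to microbial co-occurrence network topology"
author: "digestnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking digester performance to microbial co-occurrence network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digestnet)
```

## The analysis in one paragraph

Anaerobic digestion (AD) converts organic waste to methane through a chain
of microbial guilds — hydrolysers, acidogens, acetogens, methanogens — whose
cooperation can be probed without cultivation by building *co-occurrence
networks*: graphs whose edges are strong, significant rank correlations
between genus abundances across samples. `digestnet` implements the full
chain from reactor chemistry and genus tables to group-level networks and
back: derived performance metrics, community filtering and ordination,
Spearman edge selection, topology panels against random-graph baselines,
Zi–Pi ecological role classification, and correlation of network properties
with reactor parameters across groups.

## Derived reactor metrics

Free ammonia, the un-ionised and inhibitory fraction of total ammonia
nitrogen (TAN), follows the temperature- and pH-dependent equilibrium

$$FA = 1.214\cdot TAN\cdot\left(1 + \frac{10^{-pH}}
  {10^{-(0.09018 + 2729.92/T)}}\right)^{-1},$$

with $T$ in Kelvin; the functions accept °C because operating temperatures
are reported that way, and convert internally. Hydrolysis and
methanogenesis efficiency are COD balances over the reactor,

$$\eta_{hyd} = \frac{sCOD_{eff}-sCOD_{inf}+COD_{CH_4}}
  {tCOD_{inf}-tCOD_{eff}},\qquad
  \eta_{meth} = \frac{COD_{CH_4}}{tCOD_{inf}-tCOD_{eff}},$$

returned as fractions (percent formatting is presentation). Because
$\eta_{hyd}-\eta_{meth} = (sCOD_{eff}-sCOD_{inf})/(tCOD_{inf}-tCOD_{eff})$,
methanogenesis efficiency can only exceed hydrolysis efficiency when the
feed is soluble-rich — the package asserts this identity to machine
precision in its tests. The first-order hydrolysis rate constant $K_H$ is
the closed-form inversion of $S_t = S_\infty(1-e^{-K_H t})$ applied to the
hydrolysed pool (cumulative methane-as-COD plus soluble COD): by default it
is evaluated at the series midpoint — the choice of evaluation point within
the batch is genuinely open, so it is exposed as a parameter, and a
least-squares variant over all interior points is available for noisy
series. The relative differential indices
$D_{efficiency} = (\eta_{hyd}-\eta_{meth})/\eta_{hyd}$ and
$D_{rate} = (K_H - SMA)/K_H$ quantify the hydrolysis–methanogenesis
imbalance. Note that metrics of stage means differ from means of
per-sample metrics (the maps are nonlinear); both modes are supported by
passing either kind of row.

## Community preparation

Tables are samples × taxa. The network inclusion rule keeps taxa above
0.1% relative abundance in at least three samples of the analysed group —
"more than two" read strictly, and evaluated per group because networks
are built per group. Filtered tables keep abundances relative to the
*full* community rather than re-closing, so the filter is exactly
idempotent and the threshold keeps its community-wide meaning. Alpha
diversity uses natural-log Shannon $H$, genus richness, and Pielou
evenness $H/\ln(richness)$ with the single-taxon case defined as 0.
Ordination is classical metric scaling of Bray–Curtis dissimilarities;
negative eigenvalues (possible for non-Euclidean dissimilarities) are
reported and their axes dropped — no Cailliez correction, the simplest
defensible default. Group assignment is configuration-driven: clustering
can *propose* groups, but grouping decisions combine ordination patterns
with dominant-genus composition and stay a judgment call.

When one group is heavily over-sampled, `subsample_steady_state()` reduces
it deterministically (steady-state flag first, then latest stage, then
lexical sample id), so repeated runs select identical sample sets.

## Edges and their significance

All-pairs Spearman correlation uses mid-ranks for ties; an edge is kept
when $|\rho| > 0.6$ *and* $p < 0.01$. The absolute-value reading is
deliberate: digester networks contain negative associations (positive
ratios below 1), and a positive-only mode exists for sensitivity analysis.
P-values default to the two-sided t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with $|\rho|=1$ reported as $p=0$ — the
convention of the correlation tooling this style of analysis is usually
run with. Two caveats matter at the sample sizes typical of per-group
digester data:

* at $n \le 6$ the t approximation and the exact permutation distribution
  disagree by more than 0.01 in places, and at $n = 5$ only perfect
  monotone pairs can reach $p < 0.01$ at all;
* at $n = 10$ the t approximation realises roughly a 1.3% pairwise
  rejection rate at a nominal 1%.

The package therefore provides `p_method = "exact"` (full enumeration of
$n!$ orderings, $n \le 8$; the cap keeps enumeration tractable in pure R)
and `p_method = "sampled"` (Monte-Carlo permutation with the +1
correction, any $n$), both preserving observed tie patterns. The sampled
p-values are calibrated by construction but discrete and slightly
conservative; note also that the *count* of significant pairs in a matrix
is over-dispersed relative to a binomial because pairs share columns. No
multiple-testing correction is applied by default, matching the starred
single-test convention; a Benjamini–Hochberg flag exists.

## Topology panel

All topology is computed on the unweighted, sign-agnostic skeleton — the
published panels this mirrors give no weighted-metric statement, and mixing
conventions silently is worse than exposing one clearly. The clustering
coefficient is the mean *local* coefficient with degree-<2 nodes scoring 0
(the common package default; global transitivity is available under a
flag). Average path length averages over connected pairs only, with
component sizes attached. Normalized degree divides by $n-1$; normalized
betweenness by $(n-1)(n-2)/2$. The random baseline is Erdős–Rényi
$G(n,m)$ with the observed order and size (100 seeded replicates), whose
expected clustering approaches the edge density $2m/n(n-1)$. Power-law
degree fits use the discrete maximum-likelihood estimator with KS-minimal
$x_{min}$ and a parametric-bootstrap goodness-of-fit p.

Community detection must be deterministic for reproducible panels. Graphs
of ≤ 12 nodes are solved to the exact modularity optimum (integer
programming — cheap at that scale); larger graphs use greedy agglomeration
followed by a deterministic local-move refinement (each vertex offered to
neighbouring communities or a fresh singleton until no move raises $Q$),
which repairs the occasional bad merge of the plain greedy pass. Louvain
is available behind a seed.

## Ecological roles

Within-module connectivity $Z_i$ is the z-score of a node's within-module
degree over its module (population sd; degenerate sd-0 modules give
$Z_i = 0$ with a flag), and among-module connectivity
$P_i = 1-\sum_s (k_{is}/k_i)^2$ sums over *all* modules including the
node's own. Quadrant thresholds default to the widely used 2.5 / 0.62;
they are configuration, not constants, because published analyses rarely
print them. Hub rankings (by normalized degree) and gatekeeper rankings
(by normalized betweenness) are deterministic with lexical tie-breaks, and
the abundance–centrality association test deliberately highlights taxa
below 1% relative abundance appearing in top ranks — low-abundance genera
can hold central network positions.

## The synthetic community generator

Real digester sequence data cannot ship with a package, so every stage is
exercised against a simulator with known ground truth. The default
configuration emulates a 52-sample, 12-reactor, five-group design (one
deliberately over-sampled group reduced to 8 steady-state samples), with
150 bacterial and 15 archaeal genera, the archaeal block smaller and more
dominance-skewed. Within each group, taxa are randomly assigned to 4
modules; per sample each module draws a standard-normal factor and
log-abundance is baseline + (signed loading × factor) + noise, closed to
proportions, multinomially resampled at 50,000 reads and thinned by
abundance-dependent dropout (maximal near the detection limit — a genus at
several percent of a sample does not vanish from it). About 8% of taxa
load negatively, yielding negative edges and positive ratios below 1.
Loadings default to 1.6–2.4 across groups so within-module log-abundance
correlations sit near 0.97–0.99 and network density varies between groups;
group-level hydrolysis efficiency rises linearly with the group's loading
(coefficient 0.25 by default), giving topology–performance correlations a
known expected sign.

This is a test harness, not a mechanistic model: it reproduces
block-structured rank correlations, compositional closure, sequencing
noise and dropout, but not phylogenetic signal, temporal autocorrelation
within reactors, or genuine syntrophic dynamics. Passing tests therefore
demonstrate that the *pipeline* recovers planted structure under realistic
noise — not that any particular biological claim holds.

Two honest limitations surfaced by the simulator are worth knowing. First,
module recovery is evaluated on the best-powered group (13 samples), where
detected communities match planted modules with adjusted Rand ≥ 0.8; for a
five-sample group the edge rule admits only perfect monotone pairs while
chance perfect concordances (probability $2/5! = 1.7\%$ per pair) scatter
spurious cross-module edges, and no generator setting makes recovery
reliable — a caution that applies equally to real networks built over so
few samples. Second, compositional closure couples taxa across modules
(one module's surge suppresses everything else), which is a real feature
of relative-abundance data and a known source of spurious association.

## Problem sizes and runtime choices

The test suite validates every topology metric against brute-force oracles
(triangle enumeration, Floyd–Warshall with path counts, exhaustive
set-partition search for modularity) on graphs of up to 12 nodes — 100
random graphs for metric equality, 40 for partition optimality — and runs
the full pipeline on the default 52-sample fixture; the Monte-Carlo
permutation checks use 2,000–5,000 shuffles. These sizes keep the whole
suite under a minute while leaving the oracles exhaustive rather than
sampled. The pipeline itself handles the package's intended scale
(hundreds of taxa, tens of samples per group) in seconds.
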