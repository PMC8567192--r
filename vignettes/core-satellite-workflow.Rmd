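---
title: "Core/satellite sub-community analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core/satellite sub-community analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coresat)
```

## The scientific problem

Microbial metacommunities are rarely homogeneous collections of equivalent
taxa. Hanski's core/satellite dichotomy separates taxa that are widespread
and spatially *aggregated* (core) from taxa that are locally rare and
*randomly* scattered (satellite). The two groups are expected to differ in
how their composition turns over in space, in which ecological processes
assemble them, in how wide a range of habitats they use, and in how densely
they co-associate. `coresat` implements that full comparative workflow for a
rarefied OTU table with sample coordinates and a phylogeny, and ships a
synthetic metacommunity generator with known ground truth so each stage can
be validated end to end.

## Partitioning: the index of dispersion against a chi-square limit

For each OTU the index of dispersion is the variance-to-mean ratio of its
counts across all samples, zeros included, with the sample variance
(denominator n − 1, Krebs' convention). Under random (Poisson) placement
`(n−1)·ID / 1` is approximately chi-square with `n − 1` degrees of freedom,
so the upper 2.5% confidence limit is

```
limit = qchisq(1 - 0.025, df = n - 1) / (n - 1)
```

OTUs whose dispersion exceeds the limit are aggregated beyond chance and
labelled core; the remaining testable OTUs are satellite. OTUs occurring in
at most one sample have no spatial variance to test and are excluded.

Choices a user can change and why the defaults are what they are:

* `alpha_tail = 0.025` — the conventional upper 2.5% confidence line.
* `df_mode = "global"` — one limit with `df = n_samples − 1` for every OTU,
  which is what a single confidence curve over all occurrences implies.
  `df_mode = "occurrence"` (each OTU tested at `df = occurrence − 1`) is
  available for sensitivity analysis but off by default.
* Ties exactly at the limit are satellite: core requires a strictly larger
  dispersion.
* Only the upper tail is used; there is no "intermediate" class.

## Distance decay of community dissimilarity

Bray–Curtis dissimilarity is computed on the rarefied counts restricted to
one sub-community, geographic distance is the haversine great circle
(Earth radius 6371.0 km), and the decay is the OLS slope of `ln(BC)` on
`ln(distance_km + 1)` over all unordered sample pairs. Association between
the two pair vectors is tested with a one-tailed Mantel permutation test
(rows and columns of the geographic matrix permuted jointly, `+1`-corrected
p), and slope differences between sub-communities with a permutation test
that reassigns pairs between the two groups and refits both slopes each
round.

Numerical details: pairs with `BC = 0` are dropped (their log is undefined)
from both the regression and the Mantel vectors, with a reported count; a
sample with zero reads inside a subset gets dissimilarity 1 to every other
sample; distances enter in kilometres before the `+1` shift (the published
slopes this mirrors depend on that unit choice, so it is an explicit,
documented convention rather than something the package can infer).

## Assembly processes: betaNTI and Raup–Crick

Phylogenetic turnover between two samples is the abundance-weighted beta
mean nearest taxon distance (betaMNTD): for every taxon in one sample, the
patristic distance to its closest relative in the other, averaged over both
directions with relative-abundance weights (the Stegen convention;
unweighted is available via a flag). The null model shuffles taxon labels
across all tree tips, which preserves both community vectors exactly, and

```
betaNTI = (observed - mean(null)) / sd(null)
```

betaNTI ≤ −2 is read as homogeneous selection, betaNTI ≥ +2 as heterogeneous
selection. The published rule prints the lower threshold as a strict
inequality; this package symmetrizes to closed thresholds on both sides and
documents that choice. For pairs with |betaNTI| < 2, the Raup–Crick metric
on Bray–Curtis decides among dispersal processes: null communities preserve
each sample's observed richness and read total, draw members with
probability proportional to metacommunity occupancy, fill reads proportional
to metacommunity relative abundance, and the observed dissimilarity's rank
in the null distribution is rescaled to [−1, 1]. `RC ≥ 0.95` indicates
dispersal limitation, `RC < −0.95` homogenizing dispersal, and |RC| < 0.95
"undominated". One-line published descriptions of this null are famously
under-specified; the variant implemented here is the occupancy/abundance
two-step draw described above.

Efficiency note: `assembly_analysis()` shares randomizations across pairs —
each tip shuffle and each per-sample null assembly is drawn once per
replicate and reused for every pair. Marginal null distributions per pair
are unchanged; only the (irrelevant) correlation between pair-level nulls is
affected. The per-pair operations `beta_nti()` and `raup_crick_bray()` draw
independent nulls. Degenerate nulls (zero spread, e.g. a star phylogeny) are
reported as missing with a warning rather than forced to zero, and such
pairs are excluded from process fractions.

## Levins niche breadth

`B_j = 1 / sum_i P_ij^2` where `P_ij` is the proportion of OTU j's reads in
sample i (so the `P_ij` sum to one over samples). This normalization pins
`B` between 1 (perfect specialist) and the number of samples (perfect
generalist), which makes group means comparable across tables.

## Co-occurrence networks

OTUs occurring in at least 5 samples enter pairwise Spearman correlation
(midranks, zeros included); p-values come from the t approximation (the
choice of approximation is documented because exact Spearman nulls are
impractical at this scale) and are Benjamini–Hochberg corrected over all
tested pairs. An edge requires `|rho| > 0.6` and adjusted `p < 0.01`;
negative correlations count by default (a sign filter is available) and
isolated nodes are dropped. Topology is computed on the unweighted graph:
average local clustering, path length and diameter (largest component when
disconnected), Louvain modularity (best of 10 seeded restarts), and the
R-squared of an OLS power-law fit to the log-log degree-frequency
distribution. The random expectation comes from uniform Erdős–Rényi G(n, m)
ensembles with the observed node and edge counts; the ensemble's mean local
clustering has the analytic check `p = 2m/(n(n−1))`.

Stability is summarized two ways: robustness as natural connectivity
(`ln` mean exponential of adjacency eigenvalues) tracked while removing
growing fractions of nodes (random removals averaged over replicates, or
highest-initial-degree first), normalized to the intact value; and
vulnerability as the maximal relative drop in global efficiency caused by
deleting one node.

## The synthetic generator: what it emulates and what it does not

`simulate_metacommunity()` composes counts as presence (Bernoulli occupancy)
times abundance — negative binomial for core taxa (dispersion
`aggregation_k`, smaller = more aggregated), Poisson for satellite taxa —
optionally weighted by environmental filtering
`exp(-filtering_strength * (optimum - env)^2)`. Optima evolve by Brownian
motion on a unit-depth Yule tree, so close relatives prefer similar
environments: exactly the phylogenetic signal betaNTI interpretation
presupposes. Site environments are spatially autocorrelated by smoothing
white noise over an `exp(-d / spatial_decay)` kernel, which is the simplest
mechanism that makes dissimilarity rise with distance without a dispersal
simulator.

Two scale choices matter and were fixed at design time:

* **Raw abundances are cell counts, not reads.** The raw community is about
  twenty-fold larger than the sequencing depth, and the returned table is a
  multinomial subsample of it. If raw totals were near the depth, the
  subsampling would compound with the raw Poisson noise and push even
  randomly placed taxa over the chi-square limit (final dispersion is
  `1 + (depth/total) * ID_raw`); with deep raw communities the thinning
  keeps designed-satellite reads near-Poisson, which is the property the
  partition stage is entitled to assume.
* **The neutral regime carries no aggregation.** For null-model calibration
  (the tests that require |betaNTI| < 2 and |RC| < 0.95 for ≥90% of pairs),
  the neutral configuration sets `filtering_strength = 0`,
  `spatial_decay = 0` *and* a large `aggregation_k`: negative-binomial
  abundance noise is itself a form of spatial aggregation, and a "neutral"
  community that retains it is not neutral with respect to the Raup–Crick
  null.

Defaults (47 samples, 300 core + 1,700 satellite OTUs, depth 2,210 reads,
`aggregation_k = 0.3`, occupancies 0.9/0.8, `filtering_strength = 1`,
`spatial_decay = 300` km, coordinates in a high-plateau lake district
window) emulate a regional lake survey in which both selection and spatial
structure are active. What the generator does *not* emulate: sequencing
error and chimeras, duplicate sampling of the same lake, environmental
chemistry covariates, and any mechanistic hydrology — so passing
parameter-recovery tests demonstrates correctness of the statistical
machinery on data with known structure, not field realism.

## Other numerical choices

* Rarefaction subsamples reads without replacement (QIIME semantics, via
  `vegan::rrarefy`); samples below the target depth are dropped with a
  warning, never scaled.
* Chao1 uses the bias-corrected denominator `F2 + 1`, so it is defined when
  no doubletons exist; Shannon uses the natural log by default and the base
  is configurable.
* `kruskal_wallis()` uses the chi-square approximation by default. At total
  n ≤ 8 that approximation can be anticonservative by more than 0.05 in p,
  so an `exact = TRUE` mode enumerates the full permutation null; the
  default is kept for the group comparisons the pipeline runs (dozens of
  values per group), where the approximation is accurate.
* Permutation p-values use the `+1` correction and are never zero.
* All simulations and permutations accept explicit seeds; the pipeline
  derives per-stage seeds deterministically from one global seed so stages
  are independently reproducible.

## Problem sizes

The shipped tests validate the pipeline at deliberately small problem
sizes — tens of samples, a few hundred taxa, 99–199 null randomizations —
chosen so the full suite runs in minutes while keeping every statistical
check well-powered (null-model calibration pools >100 sample pairs;
parameter recovery runs at the full 47-sample survey scale, where a single
table costs well under a second). The random-graph reference ensemble uses
200 graphs, which pins two-decimal ensemble means an order of magnitude
below the tolerance used to compare them.

## Known limitations

Spearman co-occurrence on rarefied counts is not compositionality-aware
(no SparCC/SPIEC-EASI); the Raup–Crick variant is one of several in use and
results are sensitive to that choice; betaNTI assumes phylogenetic signal in
ecological niches, which the generator guarantees but real data may not;
and the distance-decay slope magnitudes depend on the distance unit inside
`ln(d + 1)`, so cross-study slope comparisons require matching conventions.
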