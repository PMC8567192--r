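# coresat

Core/satellite sub-community analysis for microbial metacommunities.

Regional surveys of bacterioplankton (e.g. 16S rRNA amplicon tables over a
lake district) usually contain a few widespread, abundant taxa and a long
tail of sparse ones. `coresat` partitions the OTUs of a rarefied sample ×
OTU table into **core** taxa — spatially aggregated beyond chance — and
**satellite** taxa — randomly scattered — and then contrasts the two
sub-communities across the standard comparative analyses of microbial
biogeography:

* **Partition** by the index of dispersion (variance-to-mean ratio of each
  OTU's counts across samples) tested against the upper 2.5% limit of the
  chi-square distribution, `qchisq(0.975, n-1)/(n-1)`; singleton-occurrence
  OTUs are excluded. Plus the abundance–occupancy regression.
* **Distance decay**: OLS of `ln(Bray–Curtis)` on `ln(km + 1)` with
  one-tailed Mantel permutation tests and a permutation test for slope
  differences between sub-communities.
* **Assembly processes** per sample pair: abundance-weighted βMNTD, βNTI
  from tip-shuffling nulls, Raup–Crick on Bray–Curtis from
  richness/reads-preserving nulls, classified into heterogeneous/homogeneous
  selection, dispersal limitation, homogenizing dispersal, undominated
  (βNTI thresholds ±2, RC thresholds ±0.95).
* **Levins niche breadth** `B = 1/Σ P²`, normalized so `B ∈ [1, n_samples]`.
* **Co-occurrence networks**: Spearman |ρ| > 0.6 with BH-adjusted p < 0.01
  over prevalence-filtered OTUs; node/graph topology, Erdős–Rényi G(n, m)
  null ensembles, natural-connectivity robustness curves, efficiency-based
  vulnerability.
* A **synthetic metacommunity generator** (Yule tree, Brownian environmental
  optima, Bernoulli × negative-binomial/Poisson counts, spatially
  autocorrelated environments, multinomial rarefaction) with ground-truth
  labels for end-to-end validation.

## Worked example

```r
library(coresat)

cfg <- synthetic_config(n_samples = 20, n_core = 80, n_satellite = 320,
                        depth = 800, seed = 42)
sim  <- simulate_metacommunity(cfg)
part <- classify_core_satellite(sim$table)
part
#> Core/satellite partition of 400 OTUs over 20 samples
#>   chi-square limit (upper 2.5%): 1.7291
#>   core: 79 (19.75%)  satellite: 37 (9.25%)  excluded: 284

core_ids <- part$otus$otu_id[part$otus$label == "core"]
ddr_fit(geo_distance(sim$metadata), bray_curtis(sim$table, core_ids),
        n_perm = 999, seed = 1)
#> Distance-decay fit over 190 pairs
#>   slope 0.0561  R2 0.107  Mantel r 0.327 (p = 0.003)

assembly_analysis(sim$table, sim$tree, n_null = 199, seed = 1)
#> Assembly processes over 190 sample pairs
#>   heterogeneous_selection   12.6%
#>   homogeneous_selection      1.6%
#>   dispersal_limitation      65.3%
#>   undominated               20.5%
```

Reading the output: 79 of the 80 designed-core OTUs clear the dispersion
limit (the generator's truth labels are in `sim$truth`); community
dissimilarity of the core sub-community rises significantly with distance
(positive slope, Mantel p = 0.003), as expected with environmental filtering
on a spatially autocorrelated gradient; and the pair-level null models
attribute most turnover to dispersal limitation and heterogeneous selection,
the signature of a spatially structured, selective landscape.

`run_pipeline(pipeline_config(...))` chains all stages (ingestion or
simulation → rarefaction → partition → diversity → distance decay →
assembly nulls → niche breadth → network) behind one seeded configuration
and writes per-stage TSV/JSON artifacts; `compare_groups()` condenses a run
into a core-vs-satellite contrast table. A thin command-line wrapper lives
at `inst/cli/coresat.R`.

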