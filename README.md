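# tilfrc

Analysis of the fibroblastic reticular cell (FRC) network and CD8⁺
tumour-infiltrating lymphocyte (TIL) compartment in lymph-node imaging mass
cytometry (IMC), for computational biologists working with multiplexed
tissue images of lymphoma (or other lymph-node pathology) cohorts.

Diffuse large B-cell lymphoma effaces the lymph node and remodels its
FRC scaffold; how remodelled FRCs and the phenotypic state of CD8⁺ TILs
organise around each other stratifies patients. `tilfrc` implements that
analysis end to end:

* **Stromal landscape** — per-pixel gating of PDPN/CD31 channels into the
  three stromal compartments (FRC = PDPN⁺CD31⁻, LEC = PDPN⁺CD31⁺,
  BEC = PDPN⁻CD31⁺), compartment area fractions, and FRC-restricted marker
  statistics (e.g. FAP⁺ FRC frequency, FRC-associated PD-L1/PD-L2).
* **Network morphometry** — Zhang–Suen skeletonisation with spur pruning
  and a branch graph (branches, junctions, geodesic lengths); gap analysis
  by greedy maximal inscribed circles on the distance transform; per-fibre
  shape features and k-means shape classes c15–c18.
* **CD8 phenotyping** — PhenoGraph-style clustering (kNN graph, Jaccard
  edge weights, Louvain modularity) of cells on arcsinh-normalised
  PD-1 / LAG-3 / TIM-3 / PD-L1 / PD-L2 / GrB intensities; normalized median
  expression heatmaps; rule-based identity assignment (nonactivated,
  progenitor exhausted, cytotoxic, terminally exhausted); FRC PD-1-ligand
  gates c11–c14; cell density and circularity (4πA/P²).
* **TIL–FRC environments (TFEs)** — per-sample cluster frequency matrix
  (cores averaged per biopsy), column z-scoring, Ward hierarchical
  clustering with silhouette-selected k; TFE1 is by convention the most
  exhausted-enriched group.
* **Spatial statistics** — Euclidean-distance-transform distances from each
  CD8 centroid to the FRC mask, cluster × TFE distance profiles, contact
  fractions, and the >10 µm "uncoupling" flag.
* **Survival** — Kaplan–Meier estimates and the log-rank (Mantel–Cox) test
  by TFE, plus Mann–Whitney U and one-way ANOVA + Tukey HSD helpers.
* **Synthetic data** — a seeded generator for TMA-like cohorts (random-walk
  fibre networks with known ground-truth graphs, phenotype archetypes,
  coupled/uncoupled cell placement, per-environment exponential survival),
  so every stage is testable without patient data.

All tabular results are tibbles; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate a 24-patient cohort (2 cores per biopsy, ~150 CD8 cells per core)
and run the full analysis:

```r
library(tilfrc)

cohort <- generate_cohort(cohort_config(n_samples = 24, seed = 42))
fit <- analyze_cohort(cohort, seed = 42)

glance(fit$tfe)
#> # A tibble: 1 × 3
#>       k n_samples mean_silhouette
#>   <int>     <int>           <dbl>
#> 1     4        24           0.621
```

Four environments are found, matching the four archetypes the generator
planted. Each CD8 cluster is mapped to a phenotype identity from its
normalized median checkpoint/GrB profile:

```r
fit$identities
#> # A tibble: 8 × 4
#>   cluster   ckpt     grb identity
#>   <chr>    <dbl>   <dbl> <chr>
#> 1 c1      0.997  0.912   terminally_exhausted
#> 2 c2      0.947  0.0926  progenitor_exhausted
#> 3 c4      0.0919 1       cytotoxic
#> 5 c5      0.0101 0       nonactivated
#> # ...
```

`ckpt` is the mean normalized median over the five checkpoint markers and
`grb` the GrB value, both on [0,1]; both high ⇒ terminally exhausted, both
low ⇒ nonactivated, checkpoints dominant ⇒ progenitor exhausted, GrB
dominant ⇒ cytotoxic. Survival stratifies by environment:

```r
glance(fit$logrank)
#> # A tibble: 1 × 4
#>   statistic    df p_value     n
#>       <dbl> <int>   <dbl> <int>
#> 1      15.9     3 0.00117    24

glance(fit$km)
#> # A tibble: 4 × 4
#>   group     n events median_survival
#> 1 TFE1      6      4            4.86
#> 2 TFE2      6      5           11.3
#> 3 TFE3      6      4           51.0
#> 4 TFE4      6      6           70.2
```

TFE1 (exhausted-enriched, spatially uncoupled) has the shortest median
survival in months and TFE4 (cytotoxic-enriched) the longest, with TFE2/3
intermediate. `autoplot(fit$km)` draws the curves,
`plot_frequency_heatmap(fit$zscored, fit$tfe)` the annotated frequency
heatmap.

Image-level work uses the same verbs per core:
`classify_stroma_pixels()` → `frc_mask()` → `skeletonize_network()` /
`gap_analysis()` / `fiber_shape_features()`, `quantify_cells()` →
`distance_to_network()`. `run_pipeline(config, out_dir)` orchestrates the
stages against a directory with content-hash caching and a run manifest.

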