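# melinvade

Tools for detecting **camouflaged invasions** of the freshwater snail
*Melanoides tuberculata* (Cerithioidea: Thiaridae) in Africa — introductions
of Asian lineages whose shells overlap morphologically with native
populations, so that they pass unnoticed without molecular and quantitative
evidence. The package is aimed at invasion biologists and malacologists who
have (1) categorical shell scores for specimens, (2) a dated or
substitution-scaled phylogeny with tip occurrence regions, and (3) invasion
localities on a gridded human-population raster, and who want the three
lines of evidence analysed in one reproducible pipeline.

## What it computes

**Morphospace.** Specimens are scored on 15 ordered categorical shell
characters with dependency-aware inapplicability (e.g. rib depth only
exists when ribs do). Borderline two-state scores collapse to arithmetic
means, mixed-data distances are built with pairwise deletion (Gower
`|x−y|/r` averaged over shared characters, or pairwise-deletion Euclidean),
and a from-scratch non-metric multidimensional scaling embeds them in 3-D
by minimizing Kruskal's stress-1

```
stress_1 = sqrt( Σ (d_ij − d̂_ij)² / Σ d_ij² )
```

with pool-adjacent-violators monotone regression (primary tie treatment),
Guttman-transform majorization, and one metric start plus 19 seeded random
starts. Native/invasive overlap is quantified by convex-hull intersection
volumes (exact point-in-hull test, seeded Monte Carlo volumes).

**Ancestral ranges.** Tip regions evolve under the equal-rates Mk model
(`P_same(t) = 1/k + (1−1/k)·e^(−kqt)`); the rate is fitted by maximum
likelihood via Felsenstein pruning, marginal posteriors are computed at
every internal node, and `call_invasions()` flags maximal clades of
focal-region tips whose *rest-of-tree* prediction puts ≥ 0.9 probability on
other regions — occurrence contradicting ancestry, the signature of a
recent introduction.

**Geographic test.** Against the null that invasion localities are random
with respect to human population: the exact probability
`(n_high/n_total)^k` that all k localities fall in the high-density group
of a raster split at 100 people/km², and a 10,000-draw resampling null of
summed per-cell population counts with a strict-exceedance empirical
p-value.

**Synthetic data.** Yule trees, Mk region evolution with plantable
"camouflaged" clades, clonal morph score matrices with tunable plasticity,
and heavy-tailed population grids with urban hotspots — so the whole
pipeline is testable end to end with no downloads.

## Worked example

The package bundles the 49-specimen shell-score table (invasive and native
morphs plus endemic Congolese comparison material):

```r
library(melinvade)

scores <- melanoides_shell_scores()
num    <- collapse_multistate(scores)
tub    <- num[num$species == "Melanoides tuberculata", ]

ord <- tub |> mixed_distance(metric = "euclidean") |>
  nmmds(dims = 3, n_starts = 20, seed = 2024)
ord
#> Non-metric MDS: 38 points in 3 dimensions
#> stress-1 x 100 = 8.621 (best of 20 starts, converged)
```

A stress of 8.6 (×100) means the 3-D embedding preserves the rank order of
shell dissimilarities well. How much do invasive and native morphs overlap
in that space?

```r
group_overlap(ord, tub[c("specimen_id", "group")], seed = 1)
#> Morphospace overlap report
#>
#> Groups:
#> # A tibble: 2 × 4
#>   group        n disparity hull_volume
#>   <chr>    <int>     <dbl>       <dbl>
#> 1 invasive    26      2.68        40.2
#> 2 native      12      2.23        27.4
#>
#> Pairwise hull overlap:
#> # A tibble: 1 × 4
#>   group_a  group_b intersection_volume overlap_fraction
#>   <chr>    <chr>                 <dbl>            <dbl>
#> 1 invasive native                 4.41            0.161
```

The invasive hull intersects 16% of the native hull's volume: shell
morphology alone cannot separate the two groups. The geographic evidence
is computed directly from the published grid split:

```r
split_probability(n_high = 76391, n_total = 988224, k = 6)
#> # A tibble: 1 × 7
#>   n_high n_total     k k_in_high     p_exact p_hypergeom p_binom_tail
#>    <dbl>   <dbl> <dbl>     <dbl>       <dbl>       <dbl>        <dbl>
#> 1  76391  988224     6         6 0.000000213 0.000000213  0.000000213
```

All six documented invasion localities sit in the ~7.7% of sub-Saharan
cells above 100 people/km²; under random placement that has probability
2.13e-07 — invasions track people. For the phylogenetic stage on your own
data:

```r
tree <- read_newick("tree.nwk")
fit  <- fit_mk(tree, read.csv("regions.csv"))   # tip_label, region
anc  <- marginal_ancestral_states(fit)
call_invasions(fit, anc, focal_region = "Africa", threshold = 0.9)
```

Each analysis also has a file-in/file-out runner (`run_morphospace()`,
`run_ancestry()`, `run_geotest()`, `run_simulate()`, `run_all()`) writing
CSV/JSON plus a reproducibility manifest, and a thin command-line wrapper
at `inst/cli/melinvade.R`.

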