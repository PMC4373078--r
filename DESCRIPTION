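Package: melinvade
Title: Detecting Camouflaged Freshwater Snail Invasions from Shells, Trees
    and Population Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect "camouflaged" invasions of parthenogenetic
    freshwater gastropods (Melanoides tuberculata and relatives), in which
    non-native lineages overlap morphologically with native populations.
    Implements a categorical shell-scoring system with dependency-aware
    missingness and arithmetic-mean collapse of borderline two-state scores;
    mixed-data distance matrices (Gower and pairwise-deletion Euclidean) and
    a from-scratch non-metric multidimensional scaling with Kruskal stress-1
    and monotone (pool-adjacent-violators) regression; equal-rates Mk
    maximum-likelihood marginal ancestral-range reconstruction on rooted
    phylogenies via the pruning algorithm, with rule-based flagging of
    invasive tips; and a two-part spatial randomization test that links
    invasion localities to gridded human population counts (density-threshold
    exact probability and a Monte Carlo null of summed per-cell counts).
    A synthetic-data module simulates Yule trees with region evolution and
    planted invasion clades, clonal morph score matrices with tunable
    plasticity, and heavy-tailed population rasters with urban hotspots, so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    cluster,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
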