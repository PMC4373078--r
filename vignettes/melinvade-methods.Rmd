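---
title: "Methods: detecting camouflaged snail invasions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting camouflaged snail invasions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

The freshwater gastropod *Melanoides tuberculata* reproduces mainly by
parthenogenesis, so local populations are near-clonal lineages ("morphs")
with characteristic shell phenotypes. Asian morphs have repeatedly invaded
African water bodies, and because some invasive morphs overlap
morphologically with native African populations, these invasions can be
*camouflaged*: undetectable from shells alone. melinvade implements the
three quantitative analyses needed to expose them — a shell-morphospace
ordination, a maximum-likelihood ancestral-range reconstruction that flags
lineages whose ancestry contradicts their occurrence, and a spatial
randomization test linking invasion localities to human population density
— together with a synthetic-data module that makes every stage testable
without external downloads.

## Shell scoring and morphospace

Specimens are scored on 15 ordered categorical shell characters (background
colour, colour patterning, columellar band, general shape, sculpture; see
`canonical_character_set()`). Three dependency rules make characters
conditionally inapplicable: patterning traits (SP, SO, HO) require some
patterning (DO > 0), band size (SC) requires a band (SH > 1), and rib depth
(RD) requires ribs (RI > 0). When two independent scorers disagreed by one
state the cell records both ("2, 3"); `collapse_multistate()` replaces such
borderline cells by their arithmetic mean, treating the state sequences as
intensity-ordered. Inapplicable cells are treated as *missing*, not as an
extra state: the rules define them as "not applicable", and coding them 0
would manufacture similarity between, say, two unpatterned shells and two
shells whose patterning merely differs.

`mixed_distance()` offers two dissimilarities, both with pairwise deletion
(each specimen pair is compared on the characters both were scored for):

* **Gower** (default): per character $|x-y|/r$ averaged over the jointly
  observed characters, with $r$ either the observed column range (default,
  matching common ecological-software behaviour) or the theoretical span of
  the character's allowed states. Distances lie in $[0,1]$. Characters with
  zero observed range carry no information and are dropped with a warning.
* **Euclidean**: $\sqrt{(p/m)\sum(x-y)^2}$ over the $m$ jointly observed of
  $p$ characters — the classical `dist()` convention of the MASS/vegan
  toolchain.

This choice was a genuinely open design point, and we settled it
empirically. On the bundled 49-row score table, Gower distances (either
range mode, any defensible row subset) ordinate at stress-1 × 100 of about
11.5–13.8, far from the published 8.99 for this analysis. Plain Euclidean
distances on the mean-collapsed scores, restricted to the *M. tuberculata*
rows that the published ordination actually displays (the endemic Congolese
*M.* cf. *liebrechtsi*/*nsendweensis* rows enter the table only as a
scoring-system demonstration), reproduce it closely: 8.62 with the
package's optimizer. The package therefore keeps Gower as the principled
default for mixed categorical data, and uses the Euclidean variant for the
historical reproduction; `scripts/acceptance.R` recomputes the latter.

### Non-metric MDS

`nmmds()` is written from scratch. Misfit is Kruskal's stress-1,

$$\sigma_1=\sqrt{\frac{\sum_{i<j}(d_{ij}-\hat d_{ij})^2}{\sum_{i<j}d_{ij}^2}},$$

with disparities $\hat d_{ij}$ from least-squares monotone regression
(pool-adjacent-violators via `stats::isoreg`) of the configuration
distances on the dissimilarity order. Ties use Kruskal's *primary*
treatment: within blocks of tied dissimilarities the configuration
distances are pre-sorted, so ties impose no constraint. The configuration
is optimized by iterative majorization (the Guttman transform); an
iteration that fails to decrease stress ends the start at the previous
configuration, making the stress trace non-increasing by construction.
Defaults: one principal-coordinates start plus 19 seeded random starts,
at most 500 iterations per start, convergence at a relative stress decrease
below 1e-7. Stress is reported ×100 (the convention under which the
reproduced ordination prints 8.99 rather than 0.0899). The returned
configuration is centered, rotated to principal axes, each axis signed so
its largest-magnitude coordinate is positive — nmMDS solutions are
otherwise only defined up to rotation and reflection. In tests the
optimizer lands within 0.5 stress units of vegan's `monoMDS` best-of-20 on
random dissimilarities.

### Overlap

`group_overlap()` quantifies the native/invasive morphospace overlap that
the ordination displays: per-group convex-hull volumes and pairwise
hull-intersection volumes (reported as a fraction of the smaller hull),
plus mean distance to the group centroid as a disparity measure. Volumes
are seeded Monte Carlo estimates (20,000 points per estimate by default,
giving absolute errors well under 0.02 on unit-scale hulls); hull
membership itself is exact, via brute-force enumeration of supporting
hyperplanes, which is robust to coplanar vertices and entirely adequate
for hulls with a few dozen vertices. Groups with fewer points than needed
for a full-dimensional hull are skipped with a warning. No significance
test of group separation is attached: the overlap is reported
descriptively, as in the source analysis.

## Ancestral ranges and invasion calls

Tip regions evolve under the equal-rates (ER) Mk model: all off-diagonal
rates equal $q$, giving the closed-form transition probabilities
$P_{ss}(t)=1/k+(1-1/k)e^{-kqt}$ and
$P_{sr}(t)=1/k-(1/k)e^{-kqt}$. `mk_loglik()` evaluates the likelihood by
Felsenstein pruning with per-node rescaling; polytomies and zero-length
branches need no special handling. `fit_mk()` maximizes over $\log q$
with bounds $[10^{-8},10^{3}]$ divided by tree height — wide enough to
cover effectively-static and effectively-randomized regimes on any branch
length scale; monomorphic data return a boundary fit with a warning. The
root prior is uniform (equal to the ER stationary distribution);
alternative priors can be supplied. The state set comes from the coding
file, not from code, and the shipped conventions follow occurrence-only
coding: a tip is coded where it occurs, even when that occurrence is a
known introduction — exactly the transparency device that lets the
reconstruction, rather than prior knowledge, reveal the invasion.

`marginal_ancestral_states()` combines the downward conditional
likelihoods with a preorder rest-of-tree pass (equivalent to re-rooting at
each node) to give each internal node's marginal posterior over regions;
the implementation is checked against exhaustive enumeration over all
internal-state assignments on small trees to 1e-9.

`call_invasions()` formalizes "ancestry contradicts occurrence". The unit
is the maximal clade of focal-region tips (a single tip in the limit), and
the decision statistic is the *rest-of-tree prediction* at the clade's
root: the distribution over regions implied by the fitted model and all
data outside the clade. The clade is flagged when at least `threshold`
(default 0.9, a declared convention — the source analysis reports clade
support rather than a probability cutoff) of that mass is non-focal. Two
properties motivated this statistic over the full marginal at nodes in or
just above the clade: inside an all-focal clade the marginal necessarily
follows the tips, so no multi-tip clade could ever be flagged; and over a
long stem branch the rest-of-tree prediction decays toward uniform, so
anciently established focal clades are not flagged even though their
ancestor was elsewhere, while lineages sitting shallowly in a foreign
clade keep a confident non-focal prediction. Recent natural dispersals
are flagged by design — they are real introductions; only their label in
a planted-truth simulation calls them "false" positives.

## Geographic randomization test

The null hypothesis is that invasion localities are a random sample of the
masked grid cells with respect to human population. Two complementary
tests:

1. **Density split** — masked cells divide at 100 people/km², converted to
   a per-cell count threshold via the cell area (21 km² by default,
   matching the resolution of the gridded population product emulated
   here); cells strictly above the threshold are "high", ties fall low.
   With all $k$ observed sites in the high group, the placement
   probability is $(n_{high}/n_{total})^k$ — independent uniform placement
   with replacement across sites, the definition under which the published
   count pair (76,391 of 988,224) reproduces the printed 2.13e-07. The
   without-replacement hypergeometric analogue is reported alongside
   (indistinguishable at that scale: the two differ in the tenth
   significant digit) and a binomial tail covers the mixed case.
2. **Resampling null** — 10,000 draws of $k$ distinct masked cells, each
   draw summing its population counts; the empirical p-value is the
   fraction of draws *strictly* exceeding the observed sum, with no
   small-sample correction — the tie-handling under which a "2 of 10,000"
   result is literally `count_exceeding / n_draws`. Multiple records in
   one cell collapse to a single site (one locality, one cell), and
   unmasked or NODATA cells are never sampled nor counted.

Because the original continental raster is not shipped, the test's
correctness is established at desk scale instead: the empirical tail
matches exhaustive enumeration of all $\binom{400}{3}$ subset sums on a
20×20 grid; under uniform placement the p-value is uniform (KS check
across 200 replicate experiments); and `power_curve()` shows rejection
rising monotonically with placement bias, near the nominal 5% at
$\beta=0$ and above 90% at $\beta=2$ on a heavy-tailed grid.

## Synthetic data: what it emulates, and what it does not

* `simulate_yule_tree()` wraps a constant-rate pure-birth simulation
  (branch lengths in units of 1/birth rate), the speciation process
  assumed for the empirical phylogeny.
* `simulate_mk_states()` evolves regions by drawing per-branch change
  counts from the ER jump process; single-branch transition frequencies
  match the closed-form matrix in tests. The camouflaged-invader scenario
  plants one clade: a clade of the requested size whose simulated states
  are all the source region has its *tips* relabeled to the focal region
  while stem and internal truth retain the source — occurrence
  contradicting ancestry by construction, with the truth table returned
  for recovery scoring.
* `simulate_character_matrix()` emulates clonal morphs: per-morph centroid
  scores drawn uniformly over valid states (respecting the
  inapplicability rules), per-specimen perturbation to an *adjacent*
  state with probability `plasticity` — an ordinal random walk, chosen
  over uniform resampling because real shell variation is graded — and a
  20% chance that a perturbed score is recorded as a borderline two-state
  cell. Plasticity 0 reproduces tight clones; within-morph Gower disparity
  increases monotonically with it.
* `simulate_population_grid()` builds lognormal background counts
  (meanlog 4.8, sdlog 2 — placing roughly 8% of cells above
  100 people/km² at 21 km² cells, the right tail the continental split
  implies) plus Gaussian-kernel hotspots, with a masked border band
  standing in for the study-region polygon. `place_invasions()` samples
  distinct cells with probability $\propto(\text{count}+1)^\beta$; the +1
  keeps empty cells reachable at any finite bias.

The invasion-recovery experiment (50 replicates in the acceptance suite)
uses 200-tip trees, $q_{true}=0.1$, states Africa/Asia/America, the root
fixed at the source region (an introduction is only meaningful against a
source-dominated backbone), and birth rate 8. The birth rate is the one
deliberately calibrated quantity: it sets total tree length ≈ 25, hence
≈ 5 dispersal events per tree at $q_{true}=0.1$ — the dispersal-limited
regime the empirical system occupies, where a phylogeny of ~79 tips
documents only a handful of intercontinental events. At much higher
dispersal (birth rate 1 gives ≈ 40 events per tree) natural recent
arrivals dominate any planted truth table, and a planted-clade recovery
criterion stops being meaningful rather than merely hard.

What passing these tests does *not* show about real data: the generator
draws characters independently given the morph (real shell characters
covary), hotspots are isotropic and the landscape otherwise spatially
uncorrelated, region evolution ignores within-region structure and
sampling bias, and trees are clock-like pure-birth — none of which the
analyses themselves assume, but all of which temper extrapolation from
simulation performance to field performance.

## Numerical choices and problem sizes

Degenerate inputs are first-class: all-zero dissimilarities, empty masks,
off-mask sites, uncoded tips, negative rates and malformed rasters or
newick files raise informative errors; zero-range characters, monomorphic
tip data and too-small hull groups degrade gracefully with warnings. All
randomness flows through explicit seeds (child seeds are derived from one
master seed and kept below $2^{31}$), and every pipeline run writes a
manifest (parameters, input checksums, seeds, package version) sufficient
to reproduce it bit for bit.

The test suite sizes its simulations for a laptop-class single core:
25-case enumeration cross-checks per operation (100 in the acceptance
suite), 200–300 replicates for distributional checks, 50 replicates for
the recovery experiment, and 500–10,000 draws per randomization run; the
full suite completes in about a minute. These sizes are the package's
declared validation conditions, chosen so Monte Carlo error stays well
inside each test's tolerance.

## Known limitations

Single-region coding only: a tip occupies exactly one region, and the
widespread-range (multi-area) generalization of ancestral-range models is
out of scope by design. Marginal reconstruction only — no joint
(max-a-posteriori path) reconstruction. The invasion call threshold is a
convention, not an error rate; it is exposed, and the recovery experiment
quantifies its behaviour only under the generator's conditions. The exact
distance metric and tie conventions behind the published stress value are
not recorded in the source; the package's reproduction is the declared
configuration above, with the Gower alternative one argument away.
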