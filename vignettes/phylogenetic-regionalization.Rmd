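---
title: "Phylogenetic regionalization with evoregio: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic regionalization with evoregio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoregio)
```

This vignette is the package's account of the science it implements:
the two regionalization models and their assumptions, the parameters
that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the underlying methods
leave details open.

## Inputs and their preparation

Both delineations start from a rooted phylogeny and a grid-cell ×
species presence/absence matrix. Trees that arrive as topology-only
supertrees are handled by two conventions applied in
`run_full_pipeline()` and available as standalone functions:

* **Missing branch lengths become 1** (`read_newick()`): with no rate
  information, every split is given equal weight.
* **Ultrametrization by terminal-branch extension**
  (`force_ultrametric()`): each terminal branch is lengthened until all
  root-to-tip depths equal the original maximum. Among the ways of
  forcing ultrametricity this is the only one that is deterministic,
  never shrinks a branch, and leaves internal branches — which carry
  the clade structure both methods read — untouched. Least-squares
  smoothing would redistribute length across internal branches and was
  deliberately not used.
* **Polytomies are resolved into zero-length bifurcations**
  (`resolve_polytomies()`), which preserves every patristic distance
  exactly; the arbitrary choice among resolutions is seed-determined.

`align_tree_and_table()` intersects the species sets, reorders table
columns to tip order, and drops empty cells. Empty assemblages are
removed because both Bray–Curtis dissimilarity and pβsim are undefined
on them; this is a hard precondition, not a preference.

## The evoregion model

The fuzzy-weighting route assumes that the *phylogenetic composition*
of a cell — not its species list — is the unit of comparison. Three
constructions, in order:

1. **Q** (`phylo_similarity_Q()`): similarity `s_ij = 1 − d_ij/max(d)`
   from patristic distances, column-standardized to unit sums. The
   kernel is bounded in [0, 1], gives `s_ii = 1`, and zeroes the most
   distant pair. The direction of standardization is a genuine choice
   (the originating literature names only "marginal totals"); columns
   were chosen so each species' profile of fuzzy belonging is a
   probability vector, matching the reading of Q as "the degree to
   which each species belongs to every other species' lineage".
2. **P** (`fuzzy_composition_P()`): row-standardized occurrences times
   Q, rows re-standardized. Rows of P are probability vectors by
   construction; this invariant is asserted on every construction.
3. **PCPS** (`pcps()`): principal coordinates of the square-rooted
   Bray–Curtis dissimilarities between rows of P. The square root is
   what keeps the spectrum essentially non-negative; residual negative
   eigenvalues beyond −1e−8 (relative) trigger a warning, and
   numerically null axes (eigenvalue < 1e−10 of the largest) are
   dropped because their scores are round-off noise. Axes explaining
   more than `retain_threshold` (default 0.05) of the variance are used
   for clustering; the 5 % default follows the established convention
   for separating interpretable turnover gradients from noise axes.

`evoregion_clustering()` then runs k-means on the retained axes for
each candidate k (default `2:10`, 25 random restarts,
seed-deterministic) and records the explained variance
(between-cluster / total sum of squares). Restarts use random
initialization; 25 restarts on the low-dimensional PCPS scores make the
explained-variance curve stable to well below the differences the elbow
rule must resolve. The number of regions is the **elbow**: the k whose
point on the curve lies farthest (perpendicular distance) from the
chord joining the curve's end points — a reproducible formalization of
"the smallest number of clusters accounting for the largest proportion
of variance". The k-means partition is finally refined by posterior
assignment from a linear discriminant analysis fit to it (the
discriminant step of DAPC); when the discriminant problem is singular,
or when reassignment would empty a cluster, the k-means labels stand.
Whether to retain a reduced set of discriminant axes was an open
choice; all retained PCPS axes are kept, because discarding axes after
the 5 % filter would apply two noise filters in a row.

Region labels are letters A, B, … in decreasing region size, ties
broken by the smallest cell id — determinism matters because labels
propagate into affiliation states and ancestral reconstructions.

## The phyloregion model

`phylo_betadiv_sim()` decomposes the tree into branch units
(`branch_incidence()`): a branch is *present* in a cell when at least
one species descending from it occurs there, and the root-to-tip path
of a species is exactly its incident branch set. Shared (`a`) and
unique (`b`, `c`) branch lengths give

`pβsim = min(b, c) / (a + min(b, c))`,

zero when one branch set nests inside the other — pure richness
difference — and one for assemblages sharing no branches. Branches
adjacent to the root count as shared whenever both cells contain
species from the same root child, the standard decomposition on rooted
trees.

Cells are clustered by UPGMA (average linkage), whose merge heights are
non-decreasing, so the implied cophenetic distances are ultrametric.
Inside `upgma()` cells are put into a canonical (sorted) order first:
exact ties — which do occur, e.g. between cells with identical
assemblages — are then broken identically whatever the input row order,
making the partition a function of the data rather than of row
arrangement.

**Choosing k** (`optimal_k()`): for each cut the explained variation is
`1 − (Σ within-group d²) / (Σ all d²)`, the fraction of summed squared
dissimilarity removed by declaring pairs "within". The quantity is
non-decreasing along nested cuts (splitting a group only removes pairs
from the within set), equals 0 at k = 1 and 1 when all groups are
internally homogeneous. The chosen k is the elbow of this curve
provided it explains at least `min_explained` (default 0.90); when the
elbow falls short, the smallest k reaching the floor is taken, and when
the floor is unreachable at `k_max` (default 20, generous headroom over
the 4–8 regions typical of regional-scale studies) the function warns
and returns `k_max`. The floor is the study-level convention; the
elbow alone can be requested by lowering `min_explained`.

## Affiliation, ancestral regions, lineage contributions

`species_affiliation()` computes exact occupancy fractions (integer
counts divided once) and assigns a species to the region holding at
least 55 % of its occupied cells, else *widespread*. The comparison is
`≥`, so a species with exactly 55 % affiliates. Two regions can never
both reach 55 %, so the rule is well defined.

`fit_mk()` treats the affiliation states — *including widespread as a
bona fide state* — as a discrete character under an equal-rates Mk
model. Widespread is a real biological condition here (range not
concentrated in any region), not missing data, which is why it is a
state rather than an ambiguity. The equal-rates model is the minimal
choice given no prior reason to privilege transitions between
particular regions; the root prior is uniform. The likelihood is
computed by Felsenstein pruning with closed-form equal-rates transition
probabilities and per-node rescaling; the rate is maximized by bounded
one-dimensional search on the log scale between 1e−8 and 500 / tree
height (rates above that bound make the transition matrix
indistinguishable from its stationary limit on every branch). An
invariant character has its maximum at rate 0; the rate is then pinned
to the lower bound with a warning.

`stochastic_maps()` samples character histories conditional on the
tips: node states are drawn jointly (root from prior × conditional
likelihood, children pre-order given their parents), then each branch's
transition history is drawn from the endpoint-conditioned process —
forward rejection first (exact, and cheap at the rates fitted here),
falling back to uniformization when a branch rejects persistently.
Because the uniformization rate is set to the true leaving rate, every
virtual jump is a real transition and the conditioned jump count has a
closed form, so the fallback is also exact. The default of 1000 maps
puts the Monte-Carlo error of node-state frequencies near ±0.03.

`evoca()` is a correspondence analysis whose columns are branch units:
the regions × species table of occupied-cell counts is projected onto
branches (branch column = branch length × summed counts of its
descendant species) and the chi-square standardized residuals are
decomposed by SVD, scores reported in principal coordinates. The total
inertia equals the Pearson chi-square of the branch table divided by
its grand total. Because inertia lives on branches but the 5 % flag is
applied to species, branch inertia is apportioned along root-to-tip
paths, shared branches divided equally among their present descendant
species; contributions then sum to exactly one, and
`species_contributions()` flags species at ≥ 5 %. The apportioning rule
is this package's recorded choice — the flag's originating usage names
no formula — and is validated by its invariants (sum to one,
permutation stability) rather than against an external reference.

## The congruence framework

`v_measure()` uses natural-log entropies with every cell weighted 1;
the analysis grid is uniform, so area weighting would only rescale all
counts. Degenerate conventions: a constant map has zero entropy, so the
corresponding component is defined as 1 and V collapses to 0 when
`h + c = 0`.

`random_regionalization()` draws the null: a rook-contiguous random
partition with the template's region count and sizes within ±10 %,
grown from random seed cells toward size targets. Nulls that preserve
contiguity and the size spectrum are *conservative* for spatially
autocorrelated maps — a cruder null (random labels) would make any
spatially coherent pair look significant. Whether the original
randomization approach preserved these properties is not documented;
both the tolerance and the null's structure are therefore exposed as
arguments for sensitivity analysis. Deadlocked or out-of-tolerance
growths restart from derived seeds (up to 100), after which the size
tolerance is relaxed with a warning rather than failing an entire
999-replicate run.

`congruence_test()` randomizes in **both directions** (A vs nulls of B,
B vs nulls of A), reports one-tailed p-values with the add-one
correction `(1 + #{V_null ≥ V_obs}) / (1 + n_rand)` — avoiding p = 0
with finite replicates — directional SES values and their mean as the
pooled SES, and flags significance only when both upper-tail p-values
are below 0.05 (the conjunction rule). Lower-tail p-values are also
reported so that *anti*-congruence is visible.

## What the synthetic generator emulates

`generate_planted_landscape()` + `generate_occurrences()` emulate the
study design both methods assume: a rectangular grid partitioned into
contiguous regions, each hosting one clade. The tree is split greedily
into as many maximal disjoint clades as regions (always splitting the
largest clade, so sizes stay near-equal within what the topology
allows), clades pair with regions by decreasing size, and a member
species occupies home-region cells with probability `p_in` and others
with `p_out`. Widespread species are drawn uniformly from the tips
after clade assignment and occupy every cell with probability
`(p_in + p_out)/2`, mimicking the widespread category without
favouring any region. The grid is abstract (row, col) with unit
spacing: the analyses consume only cell identity and rook adjacency, so
no geographic projection is needed.

Defaults `p_in = 0.9`, `p_out = 0.05` represent a strong but noisy
clade-in-region signal — roughly two stray species per cell at 48 tips
— which is the regime the recovery experiments target. What the
generator does **not** emulate: range cohesion within a region (cells
are occupied independently), environmental gradients, richness
gradients, detection error, or clades spanning several regions. Passing
recovery tests therefore demonstrate that the pipelines decode the
clade-in-region signal they were designed for; they do not demonstrate
robustness to the spatial and ecological structure of real occurrence
data.

## Validation design and problem sizes

The test suite validates every statistic against an independent route:
V-measure against a mutual-information oracle on exhaustive small
contingency tables; pβsim against explicit branch-set enumeration on
random trees of up to 8 tips; the pruning likelihood against exhaustive
summation over ancestral-state combinations (and against an independent
Mk implementation); stochastic-map node frequencies against enumerated
marginal posteriors on a 6-tip fixture; evoCA inertia against the
Pearson chi-square; UPGMA cophenetic matrices against the ultrametric
three-point condition.

Recovery experiments use 48-tip trees on 20 × 20 grids with four
planted regions (`p_in = 0.9`, `p_out = 0.05`, no widespread species,
five seeds, four of five required): both pipelines must select k = 4
and reach adjusted Rand ≥ 0.9 against the planted map. Null-model
calibration uses 20 independent random map pairs (n_rand = 199) and a
super-uniformity check over 200 small-grid tests (n_rand = 49). These
sizes were chosen as the smallest at which the signal regime of the
generator is unambiguous while the full suite stays comfortably
runnable on a laptop.

## Known limitations

* The fuzzy-weighting construction follows the published description of
  Q and P, not the original authors' code; the similarity kernel and
  standardization direction are recorded choices, and alternative
  kernels would shift PCPS scores (though rarely the partition).
* k-means restarts make the elbow curve stable, but on weakly
  structured data the elbow itself is genuinely ambiguous; inspect the
  stored `diagnostics` curve rather than trusting k̂ blindly.
* The Mk machinery is equal-rates only; ordered or all-rates-different
  regimes (e.g. stepping-stone dispersal between adjacent regions) are
  out of scope.
* Congruence p-values are per-comparison; no multiplicity correction is
  applied across a table of comparisons.
* With ~2000+ cells the pβsim and PCPS stages hold dense cell × cell
  matrices in memory; this is fine at regional grid sizes but the
  package makes no attempt at sparse or out-of-core computation.
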