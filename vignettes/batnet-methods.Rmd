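---
title: "Methods: weighted bipartite network analysis in batnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted bipartite network analysis in batnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batnet)
```

# The data model

`batnet` analyses weighted bipartite interaction networks: a consumer guild
(rows, bats) and a resource guild (columns, plants), with the cell value
`A[i, j]` counting realised interaction events — in the molecular diet
setting, the number of individual bats of species *i* whose faecal sample
contained DNA of plant taxon *j*. Counts are integers by definition; the
reader accepts integral-valued decimals because count matrices round-tripped
through spreadsheet tools often acquire a `.0`.

Every metric presupposes a *hygienic* matrix: no all-zero rows or columns.
Subsetting a field matrix by season or site routinely creates empty margins,
so `drop_empty()` is an explicit, logged step rather than something metrics
do silently. Orientation is fixed (bats in rows); transposed files must be
declared with `transpose = TRUE` rather than auto-detected, because
orientation guessing is unsafe for square-ish matrices.

# Structure descriptors

Five descriptors characterise a network, written for a matrix with `R` rows,
`C` columns, `L` nonzero cells and total weight `T`:

* **Connectance** `L / (R * C)` — the realised fraction of possible links.
* **Compartments** — connected components of the bipartite graph on the
  nonzero cells (via `igraph`). Components are numbered by decreasing size so
  "compartment 1" is always the dominant one.
* **WNODF** — weighted nestedness by overlap and decreasing fill
  (Almeida-Neto & Ulrich 2011). For an ordered row pair with strictly
  decreasing marginal totals, the poorer row contributes the percentage of
  its occupied cells whose weights are strictly smaller than the richer
  row's corresponding cells; ties and equal marginal totals contribute
  nothing. The same applies to column pairs, and the index is the mean over
  all `R(R-1)/2 + C(C-1)/2` pairs. The classic index lives on 0–100; reports
  use the 0–1 rescaling (`scale = "raw"` exposes the classic value), since
  published bat–plant values are printed on the unit scale.
* **Barber modularity** `Q = (1/T) * sum_ij (A_ij - k_i d_j / T) 1[g_i = h_j]`
  for a joint module assignment `(g, h)` of rows and columns. `Q` is
  reported unnormalised, matching the value returned by weighted bipartite
  modularity optimisers.
* **WNODF_SM** — WNODF restricted to same-module row pairs and same-module
  column pairs, the nestedness half of a compound topology (modular network
  with internally nested modules). It is computed conditional on the single
  best partition found for the network, with the same seed as the report; if
  the partition leaves no same-module pair, the metric is undefined (`NA`).

## Module search (DIRTLPAwb+)

`find_modules()` maximises `Q` with the DIRTLPAwb+ strategy (Beckett 2016):

1. *Label propagation* (LPAwb+ stage 1): alternating between guilds, every
   node adopts the opposite-guild module label with the largest positive
   summed modularity-matrix contribution; a node with no helpful label
   retreats to its own singleton module. Sweeps repeat until `Q` stops
   improving by more than `1e-10`.
2. *Agglomeration* (stage 2): the module pair whose merger yields the
   largest positive `Q` gain (read off the module-pair contribution matrix)
   is merged, propagation is re-run, and the process repeats until no merge
   helps.
3. *DIRT restarts*: the whole procedure restarts from random initial
   labelings with initial module counts `{1, 2, 4, ..., min(R, C)}`
   (`reps = 10` restarts per count by default, plus one deterministic
   baseline with every row in its own module), keeping the best `Q`.

All randomness flows from one integer seed; ties in label choice resolve to
the smallest label id, so results are reproducible bit for bit. The returned
partition is canonicalised: module ids `1..m` by decreasing within-module
link weight. Label propagation is a heuristic: on tiny networks the suite
checks it against exhaustive partition enumeration as an upper bound and
against planted block structure for exact recovery, but global optimality is
not guaranteed in general — hence the restarts, and hence reporting `Q`
from the best of many starts, as the published algorithm does.

# Null models and z-scores

Two randomisations benchmark the descriptors, each preserving features a
"no structure beyond sampling" explanation would already grant:

* **vaznull** preserves dimensions, `L`, `T` and full coverage (every
  species keeps at least one link), and conserves marginal totals
  *probabilistically*: cells are selected with probability proportional to
  the product of observed margins. Stage 1 places `L` distinct weight-1
  cells sequentially; stage 2 distributes the remaining `T - L` events over
  the filled cells with the same probabilities renormalised.
* **The module-conserving null** additionally fixes the observed modular
  skeleton: the matrix is cut into regions by module pair, and vaznull runs
  independently inside each region that holds observed links, preserving
  regional fill and weight. Within-module regions keep coverage of every
  member with an observed within-module link; between-module regions carry
  no coverage requirement by default (coverage of the whole matrix is
  already guaranteed by the diagonal regions) — `strict = TRUE` switches the
  requirement on, since published descriptions of this null leave the
  between-module constraint open.

A z-score is `(observed - mean(null)) / sd(null)` with the sample (n−1) sd
over `n` replicates (study convention: 1000); conserved quantities have zero
null variance and an undefined (`NA`) z. Reports pair WNODF and modularity
with vaznull, and WNODF_SM with the module-conserving null, whose replicates
are evaluated at the observed partition (the structure it conserves);
vaznull replicates re-detect modules from scratch.

Two numerical points deserve record. First, the sequential stage-1 fill
needs a feasibility guard so that late cells can still cover species without
links; since a single cell can cover an uncovered row and an uncovered
column simultaneously, the guard is `max(uncovered rows, uncovered cols) <=
remaining cells` — the tightest conservative bound; a sum-form bound would
deadlock on matrices where `L` equals `max(R, C)`. With this guard the
sequential construction essentially never dead-ends, but a bounded retry
(1000 restarts) backstops it, and `null_distribution()` aborts if more than
10% of replicates fail. Second, "probabilistically conserves margins" is not
"conserves margins in expectation at arbitrary precision": conditioning on
full coverage and on `L` distinct cells shrinks extreme margins toward the
mean by a few tenths of an event on study-sized matrices. That shrinkage is
a property of the null model family itself, visible in any faithful
implementation once the Monte-Carlo standard error of the null mean drops
below it (around a thousand replicates); comparisons of observed margins to
the null spread remain well-behaved.

# Interaction dissimilarity

For two networks, `beta_S` is the Soerensen dissimilarity
`(b + c) / (2a + b + c)` over the pooled species sets of both guilds
(matching is exact label within guild). Interaction dissimilarity follows
the rewiring/turnover decomposition: `beta_WN` is the Soerensen
dissimilarity of the full link sets (links are binary — the pair of
endpoint labels, weights ignored); `beta_OS` is the same dissimilarity
computed on the subnetworks induced on species present in both networks,
isolating rewiring among shared species; `beta_ST = beta_WN - beta_OS` is
the remainder attributable to species turnover, additive by construction.
When the shared-species subnetworks contain no links at all, `beta_OS` is
undefined and `beta_ST` is reported equal to `beta_WN` with a flag
(`os_undefined`). Soerensen (2a) denominators are used throughout, matching
the default of the betalink framework these quantities come from; no
weighted (Bray–Curtis) variant is offered because the decomposition is
defined on link identity.

# Sampling completeness

Chao1 estimates the true richness of a class system from singletons and
doubletons: classic `S_obs + f1^2 / (2 f2)`, bias-corrected
`S_obs + f1(f1-1) / (2(f2+1))`; the classic form falls back to the
bias-corrected one when `f2 = 0`, flagged. For *network* completeness the
classes are the realised links and a link's abundance is its cell count
(each detection event is one "individual"), and completeness is
`100 * L / Chao1` percent. Both variants are exposed because published
supplementary materials rarely state which was used; classic is the default.
Per-species diet accumulation uses exact individual-based rarefaction,
`E[S_n] = sum_k (1 - choose(N - N_k, n) / choose(N, n))`, evaluated in log
space (`lchoose`) so large counts do not overflow; the suite checks it
against Monte-Carlo subsampling. Note the boundary behaviour of the strict
"more singletons, lower completeness" intuition: adding the *first*
singleton to a network with none leaves the bias-corrected estimate at
`S_obs`, so completeness can stay flat exactly at that boundary.

# The synthetic generator

Real deposited matrices cannot ship with the package, so a generator plants
known structure and lets every pipeline stage be exercised offline:

* Species get lognormal abundance weights (`abundance_sd`); cell
  probabilities are proportional to the product of endpoint abundances —
  the classic abundance argument for nestedness, which makes comparison
  against vaznull meaningful on synthetic data.
* A round-robin module assignment multiplies same-module cells by
  `affinity_ratio`, planting block-modular structure (1 = none).
* `T_events` detection events are drawn from the categorical cell
  distribution and the count matrix passes through `drop_empty()`.

Defaults were fixed once to emulate a single-forest whole-year study
network: 12 bat and 22 plant taxa, 3 modules, 130 events,
`affinity_ratio = 30`, `abundance_sd = 0.7`. Under these settings generated
networks average modularity near 0.55 and WNODF near 0.14, the regime the
field data occupy. Two departures from real data are known and accepted:
multinomial event sampling spreads detections more evenly than real repeat
detections cluster, so generated connectance runs slightly high (~0.24
vs ~0.19) and Chao1 completeness slightly low (~60% vs ~80–95%); and module
sizes are balanced by construction, unlike field modules. Passing tests on
synthetic data therefore demonstrate correctness of the algorithms under
planted structure, not distributional realism of every descriptor.

`generate_season_pair()` derives a second "season" from a base network with
two planted drivers: a turnover fraction `tau` of each guild is *replaced*
(not deleted — replacements inherit the degree of the species they replace,
keeping network size comparable, as in real season pairs where richness
changes modestly), and a rewiring fraction `rho` of the links among retained
species has its plant endpoint moved to a different shared plant, avoiding
duplicate links. Counts are resampled over the new link set with every link
keeping at least one event. Across a `rho`/`tau` grid, `beta_OS` tracks
`rho` and `beta_ST` tracks `tau` on average, which is the recovery property
the dissimilarity module is tested against.

# Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data at
deliberately modest sizes: fuzz networks with `R + C <= 8` against
brute-force oracles (1000 cases), 1000-draw null contracts on a 10×10
matrix, 20-replicate grids for recovery checks, and 200-replicate null
ensembles with 6 restarts per module count in the end-to-end script. These
sizes give stable averages while keeping a full run in minutes on one CPU;
the study-scale convention (1000 nulls, 10 restarts) remains the default of
the user-facing functions. Every stochastic path takes one integer seed;
batch runs derive independent per-task seeds from it with a counter scheme,
so adding a network to a batch never changes the results of the others.

# Reproducing the original study tables

`reproduce_study(data_dir)` runs the complete pipeline (structure reports
with z-scores, the dissimilarity table, the completeness table) over a
directory of deposited interaction-matrix CSVs. The matrices of the source
field study are archived on DRYAD (doi:10.5061/dryad.0rxwdbs29) and are not
redistributed here; with that directory supplied, the deterministic cells
of the published metrics table (richness, compartments, connectance, WNODF)
should reproduce exactly and the stochastic ones (modularity, WNODF_SM,
z-scores) within seed-to-seed variation.

# Known limitations

* Label propagation can miss the global modularity optimum on adversarial
  instances; restarts mitigate but do not eliminate this, exactly as with
  the published algorithm.
* The between-module constraint of the module-conserving null is
  interpreted per region pair; other published variants may constrain the
  off-diagonal blocks jointly. The `strict` switch covers the plausible
  alternatives.
* No coverage-based (Chao–Jost) extrapolation or interval estimates for
  completeness; no weighted dissimilarity indices; no binary NODF or other
  nestedness families — the pipeline implements exactly the descriptor set
  it was designed around.
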