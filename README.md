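# batnet

Analysis of weighted bipartite ecological interaction networks, built for
molecular (faecal-DNA) bat–plant diet data: bats in rows, plant taxa in
columns, and each cell counting the individual bats in whose faeces that
plant's DNA was detected. The package serves ecologists who want to
characterise such networks structurally, benchmark the structure against
constrained null models, compare networks across sites or seasons, and
assess how completely the interactions were sampled.

## What it computes

For a hygienic interaction matrix with `R` bats, `C` plants, `L` links and
total weight `T`:

* **Connectance** `L/(R·C)` and **compartments** (connected components of
  the bipartite graph).
* **WNODF** — weighted nestedness by overlap and decreasing fill: for each
  pair of rows with strictly decreasing marginal totals, the share of the
  poorer row's occupied cells that are strictly smaller than the richer
  row's, averaged with the analogous column pairs (0–1 scale; the classic
  0–100 value is available).
* **Barber bipartite modularity**
  `Q = (1/T) Σᵢⱼ (Aᵢⱼ − kᵢdⱼ/T)·1[gᵢ = hⱼ]`, maximised with the
  DIRTLPAwb+ strategy (label propagation + greedy agglomeration + random
  restarts), and **WNODF_SM**, nestedness restricted to same-module pairs
  (the compound-topology diagnostic).
* **Null models and z-scores** — the vaznull randomisation (conserves
  dimensions, connectance, total weight, coverage; probabilistically
  conserves margins) and a module-conserving extension of it, with
  `z = (obs − mean(null))/sd(null)` over seeded replicate ensembles.
* **Interaction β-diversity** — `β_S` (species composition), `β_WN` (whole
  link sets), `β_OS` (links among shared species: rewiring) and
  `β_ST = β_WN − β_OS` (species turnover), Sørensen family, links binarised.
* **Sampling completeness** — Chao1 (classic and bias-corrected) over link
  abundances, reported as `100·L/Chao1` percent, plus exact
  individual-based rarefaction curves of per-species diets.
* **Synthetic generators** — networks with planted modules, abundance skew
  and seeded determinism, and paired "seasonal" networks with planted
  rewiring (`rho`) and turnover (`tau`) fractions, so the full pipeline is
  testable without any field data.

## Worked example

```r
library(batnet)

g <- generate_network(seed = 42)     # study-scale synthetic network
net <- g$network
net
#> <bipartite_network> 12 bats x 19 plants, L = 54 links, T = 130 events

report <- structure_report(net, nulls = 200, reps = 6, seed = 42)
report
#> <structure_report>
#>   plant richness 19, bat richness 12, compartments 1
#>   WNODF        0.14 (z = -2.8)
#>   modularity   0.60 (z = 8.7)
#>   WNODF_SM     0.42 (z = -1.4)
#>   connectance  0.24, completeness 65.22%

pair <- generate_season_pair(rho = 0.4, tau = 0.2, seed = 42)
interaction_beta(pair$net_A, pair$net_B)
#> <beta_report> beta_S = 0.194, beta_WN = 0.564, beta_OS = 0.385, beta_ST = 0.179
```

Reading the report: the network is one connected compartment; nestedness
(WNODF 0.14) sits *below* the vaznull expectation (z = −2.8) while
modularity (Q = 0.60) sits far above it (z = 8.7) — the planted modular
structure is real and not explained by margins alone. WNODF among
same-module species (0.42) is higher than whole-network WNODF but close to
the module-conserving null (z = −1.4), and the Chao1 completeness of 65%
says a third of the link richness likely went undetected at 130 events. In
the seasonal comparison, most interaction dissimilarity (β_WN = 0.56) comes
from rewiring among shared species (β_OS = 0.39) rather than from species
turnover (β_ST = 0.18), consistent with the planted rho > tau.

Field matrices enter through `read_network_csv()` (header = plant labels,
first column = bat labels) or `read_edge_list_tsv()`, followed by
`drop_empty()`; `analyze_networks()`, `beta_table()` and
`completeness_table()` run batches, and `reproduce_study()` points the
whole pipeline at a directory of deposited matrix CSVs.

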