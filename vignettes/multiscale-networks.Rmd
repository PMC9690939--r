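---
title: "Multi-scale ecological networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale ecological networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoscapenet)
```

## The model in one page

An ecological network is a graph whose nodes are habitat source patches and
whose edges are least-cost movement corridors. Because a 10-ha-ranging
rodent and a 100-km-ranging ungulate experience the same landscape
completely differently, everything is computed five times, once per
dispersal scale — a fixed pairing of minimum habitat area and maximum
dispersal distance (10 ha/3 km, 60 ha/10 km, 300 ha/30 km, 500 ha/60 km,
1000 ha/100 km). The pipeline is:

vegetation foreground → MSPA classes → source patches (per scale) →
resistance surface → least-cost corridors (per scale) → connectivity
indices → ecological groups → group evolution across years.

The key modelling assumptions are: (i) movement cost is additive over an
8-connected raster, with a step costing its length times the mean
resistance of the two cells; (ii) movement probability between patches
decays exponentially with accumulated cost, anchored so that the
probability equals `p = 0.05` at the species' maximum dispersal distance;
(iii) patch "quality" enters all indices only through its area (the patch
attribute `a`); and (iv) a corridor is ecologically meaningful only when
it does not cross a third source patch and its cost distance fits in the
scale's dispersal budget.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `edge_width` (MSPA) | 1 | cells (30 m) | smallest non-degenerate erosion width; the class map is sensitive to it, so it is exposed everywhere |
| factor weights | 0.32/0.27/0.22/0.19 | — | fixed weighted-overlay constants (land use, distance to construction, slope, elevation); treated as given, not re-derived |
| `p` | 0.05 | probability | movement probability at the maximum dispersal distance; sets the decay constant `α = −log(p)/d` |
| `r_ref` | 1 | resistance | converts a dispersal distance into a cost budget: a pair enters the network iff `lcd ≤ max_km·1000·r_ref`, i.e. the cost of covering the distance over ideal habitat. The budget's units are a genuinely open choice; cost units with `r_ref = 1` is the strictest consistent reading and is configurable |
| `band_frac` | 0.1 | fraction of cwd | extra cost allowed when collecting the corridor band for the width metric; 0 collapses the band to the optimal path cells |
| `tau` | 0.2 | fraction | relative member-count change separating stability from expansion/shrinkage in event classification |

## What the synthetic generator emulates — and what it does not

`scenario_config()` produces a multi-temporal scene with the statistical
features the analysis relies on:

* **Separated vegetation clusters with internal structure.** Each macro
  region holds one main forest block (a geometric ladder of target areas,
  roughly 1150 → 14 ha on the default 360×360 grid so that every scale
  keeps a non-trivial, strictly nested source set: 18/5/4/3/2 patches)
  plus two satellite patches tied to the main block by shrub strips. A
  one-cell grassland fringe around each block guarantees that MSPA erosion
  consumes fringe rather than core, so core areas land on their targets.
* **Barriers.** A connected three-cell river follows low elevation through
  the inter-region margin, and farmland margins of fixed width (180 m)
  separate the clusters, so corridor routing is non-trivial and the five
  dispersal budgets bite at different gaps.
* **Lowland-skewed relief.** Four octaves of bilinearly upsampled noise,
  min–max rescaled and raised to the third power before scaling to
  `relief_amplitude` (default 600 m). The skew mimics a delta landscape —
  a broad plain under the 100 m resistance break with localised uplands —
  and matters: without it, mid-elevation terrain alone (resistance class
  200 at 100–200 m) prices even short corridors out of the 3-km budget.
* **Monotone urbanisation.** Construction accretes onto the urban frontier
  by exactly `round(growth · ncells)` cells per step (default 2% per
  decade), never into water, and fails loudly when the frontier is
  exhausted.

It does **not** emulate: classification noise or mixed pixels, seasonal or
gradual land-cover transitions, hydrologically conditioned DEMs,
species-specific habitat suitability within the vegetation classes, or the
empirical patch-size and gap-size distributions of any real region.
Passing tests on these scenes therefore demonstrate algorithmic
correctness and qualitative scale behaviour (nested source sets, group
counts falling with dispersal distance), not calibrated regional
predictions.

## Numerical choices and conventions

* **Raster geometry.** Row 1 is north; cell `(r, c)` centres at
  `(x0 + (c−0.5)h, y0 − (r−0.5)h)`. Cell area is `h²/10⁴` ha (0.09 ha at
  30 m). Rasters are exchanged as plain-text ESRI ASCII grids.
* **Morphology.** Box (Chebyshev) erosion/dilation; cells beyond the
  raster are background. Foreground connectivity is 8, hole detection uses
  the dual 4-connectivity. Class precedence on the non-core rind is
  perforation over edge. Connector components are subclassed by the core
  components their geodesic neighbourhood touches (≥2 → bridge; one core
  at ≥2 separate contact sites → loop; otherwise branch).
* **Class intervals.** Reclassification intervals are closed on the upper
  bound — slope 15° is still class "0–15", elevation 100 m is "≤100". The
  published class tables print shared endpoints without a rule; one had to
  be fixed, and this one is asserted in tests.
* **Least-cost machinery.** The cell graph uses igraph's Dijkstra; patch
  distances are boundary-to-boundary via a zero-cost virtual vertex wired
  to all patch cells. Equal-cost tie-breaking is igraph's deterministic
  internal order, so corridor counts are reproducible; cwd values are
  tie-break independent and are checked cell-exactly against an
  independent plain-R Dijkstra.
* **PC.** The probability-of-connectivity uses the standard area-weighted
  maximum-product-probability kernel normalised by the squared total
  landscape area, with `p*ᵢᵢ = 1` and zero contribution from unreachable
  pairs. The max-product path is found exactly as a shortest path on edge
  length `α·lcd` (log transform).
* **BCPC.** Endpoints are excluded from the accumulating path interior
  (the subscripts of the definition say `i ∈ P_jk`, `k < j`; the
  alternative endpoint-inclusive reading is rejected as it would make
  every patch its own stepping stone). The optional fusion with a
  dPC-connector weighting is off by default.
* **Current flow.** Edge conductance is `1/lcd`. For each grounded focal
  patch, unit currents are injected at every other patch of its component
  and the reduced Laplacian solved directly; a node's through-current is
  half the sum of absolute incident edge currents plus half its net
  injection. Isolated patches get 0. Node currents are invariant under
  uniform conductance scaling (asserted).
* **Modularity.** The printed community-quality formula is typographically
  garbled in its source; the standard weighted Newman modularity
  `q = Σ_C [w_in/m − (deg_C/2m)²]` is used, consistent with the stated
  principle (dense inside, sparse between) and with igraph's
  implementation (asserted to 1e−12). Greedy agglomeration always merges
  the pair with the best Δq (ties to the smallest pair indices), records
  all n…1 levels and returns the best level.
* **Cores and evolution.** `Cen(v)` sums weight differences over
  whole-graph neighbours (a scope option restricts to the own group);
  `Cen = 0` — including the isolated-node empty sum — is *not* core, per
  the strict inequality. Patch identity across years is by ≥50% cell
  overlap, greatest overlap winning. Groups without cores participate in
  evolution only as formation/disappearance endpoints. Many-to-many
  relation tangles are resolved by strongest-overlap pairing before
  re-classification, so every group lands in exactly one event.
* **Degenerate inputs.** Empty foreground → valid all-background MSPA map
  with flagged zero proportions; no construction → infinite distances
  mapped to the most distant class; `V < 3` → α and γ flagged `NA`;
  `PC = 0` → dPC flagged; total edge weight 0 → modularity flagged and the
  singleton partition returned; min–max normalisation of a constant
  column → 0 for all nodes.

## Known limitations

* Greedy agglomerative modularity is *not* uniformly near-optimal: on
  small random graphs the test suite documents instances where its q stops
  at ~90% of the exhaustive optimum — with the reference CNM
  implementation (igraph) returning exactly the same value. Results
  involving marginal community structure should be read accordingly;
  recovery of clear-cut structure (e.g. disconnected components) is exact.
* The dispersal gate compares cost distance against a distance-derived
  budget; with `r_ref = 1` this is deliberately strict, and corridor
  counts are therefore lower than tools that gate on geometric length.
* Corridor width depends on the band budget (`band_frac`), for which no
  published rule exists; comparisons should hold it fixed.
* Current flow solves a dense reduced Laplacian per grounded patch —
  fine for the hundreds of patches typical here, not for 10⁵-node graphs.

## Problem sizes

The shipped scenarios are sized so the full suite runs in minutes on one
core: the default demonstration scene is 360×360 cells (11,664 ha) with
four decades and five scales; unit tests use 9×9 – 240×240 fixtures; the
least-cost oracle sweep uses 200 random grids up to 25×25; exhaustive
path/partition oracles run on graphs of up to 8 nodes (4140 partitions).
All randomness is seeded; identical configurations reproduce reports byte
for byte.
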