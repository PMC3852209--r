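---
title: "Mining dense tumor–stroma co-expression BiNets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining dense tumor-stroma co-expression BiNets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binetminer)
```

## The model

`binetminer` treats cross-tissue co-expression as a weighted bipartite graph
G = (V<sub>X</sub>, V<sub>Y</sub>, E): tumor genes on side X, stroma genes
on side Y, and an edge wherever the Pearson correlation between a tumor
gene's profile and a stroma gene's profile across K matched samples reaches
the construction threshold, with the correlation as the weight. Three
modeling assumptions follow from this choice:

* **Nonnegative weights.** Density arithmetic and the growth guarantee
  presuppose weights in (0, 1]. By default only correlations
  ρ ≥ `min_weight` > 0 become edges; `absolute = TRUE` folds negative
  correlations in as |ρ| for exploratory use, at the cost of conflating
  activation and repression.
* **Absent edges are zeros.** Sub-threshold correlations contribute 0 to
  every density and contribution sum, consistent with a sparse thresholded
  construction.
* **Linear association.** Pearson correlation only sees linear
  co-variation; profiles must be variance-filtered first, since
  low-variation genes yield unstable correlation estimates
  (`build_coexpression_graph()` refuses constant profiles outright).

## Mining and its guarantee

A BiNet B with side sizes a and b has density
d(B) = Σ w(e) / (ab); a candidate vertex's contribution is its mean edge
weight into the opposite member set. Mining is greedy seed-and-grow
(`bcm_mine()`): edges are visited in descending weight order, every
unselected edge with weight ≥ β·w<sub>max</sub> seeds a component, and each
growth step admits the better of the two sides' best candidates iff its
contribution is at least α·d(B), with

α = 1 − 1/(λ(i+τ+1)),  λ = max{1, C/(i+τ+1)²}

for current side size i. The schedule is the whole point: a step admitted at
size i can shrink the density by at most the factor (i+α)/(i+1), and
telescoping those factors over both sides gives the closed-form floor
implemented in `density_bound()`:

F(C, τ) = ((2C−τ−2)/(2C))^{2k} · ((√C−τ−1)/(√C−τ))²,  k = max(0, ⌈√C−τ−1⌉−1).

Every mined BiNet therefore satisfies d(B) ≥ F(C, τ) · w(seed), which
`verify_density_bound()` re-checks against the graph. The implementation is
deliberately faithful to the greedy scheme rather than to any relaxation:

* Ties for "best contribution" go to the smallest vertex id, and equal best
  contributions across sides go to the Y side. Neither choice affects the
  guarantee; both make results exactly reproducible.
* Growth terminates the first time the *winning* side fails its α test,
  even if the losing side might still pass. This is the conservative
  reading of the alternating scheme; it can only stop earlier, so the bound
  is unaffected.
* The seed edge itself is marked selected at creation, making the Selected
  set a complete record of covered heavy edges; vertices may still be
  shared across BiNets.
* α is *piecewise* monotone in the side size: it decreases as
  1 − (i+τ+1)/C while (i+τ+1)² < C, then increases as 1 − 1/(i+τ+1). The
  early permissiveness lets small components accept slightly weaker
  vertices; the late tightening keeps large components dense.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `C` | 36 | schedule scale; must exceed (τ+2)². Larger C pushes F toward 1 but admits fewer vertices |
| `tau` | 2 | schedule offset; softens the early α values |
| `beta` | 0.7 | seed-weight fraction of w<sub>max</sub>; lower values enlarge the search space |
| `min_weight` | 0.6 | graph construction threshold on ρ (dimensionless correlation) |
| `min_genes` | 10 | distinct-gene floor for biomarker-sized BiNets (union of both sides) |
| merge `threshold` | 0.3 | minimum merged density of a macro network |

At the defaults, `density_bound(36, 2)` evaluates to
`r round(density_bound(36, 2), 4)`: every reported BiNet is guaranteed at
least ~45% as dense as its seed edge is heavy. The construction threshold
`min_weight = 0.6` is a package default chosen to keep the graph sparse at
biologically plausible correlation levels; it is recorded in the graph's
metadata attribute, and all downstream artifacts carry it.

## Merging BiNets into macro networks

`merge_binets()` summarizes BiNets with best-first agglomerative merging:
start with one cluster per BiNet, repeatedly merge the pair whose *union*
density (recomputed exactly on the graph) is maximal, while that density
stays at or above the threshold; ties go to the smallest pair of cluster
ids. Candidate densities are recomputed after every merge — no lazy
approximation — because with hundreds of BiNets the O(k²) round cost is
negligible. The merge order is by union density; other linkage orderings
are possible, and the dendrogram (exported as Newick, branch lengths =
merge density) documents the ordering actually used. Because the merge
sequence does not depend on the threshold (only the stopping point does),
relaxing the threshold can never increase the number of macro networks.

## Survival evaluation

Each BiNet's combined gene set (union of sides) becomes the feature set for
patient stratification. `two_group_split()` is K = 2 clustering under the
city-block (L1) distance with component-wise **median** centroid updates —
the L1-optimal centroid — restarted 100 times from random pairs of
observations; the restart with the lowest total within-cluster L1 cost wins,
ties to the first found. Features are used on their own scale by default
(`standardize = TRUE` z-scores them). `logrank_test()` compares the two
groups with the standard log-rank chi-square on 1 df (computed via the
`survival` package; censored samples leave the risk set at censoring). A
split in which all feature rows are identical is flagged degenerate and not
tested. For reporting, group 1 is oriented as the lower-event-rate (better
outcome) group; orientation never touches the statistic. Raw p-values are
reported by default, with Benjamini–Hochberg adjustment behind
`p_adjust = "BH"`; the per-cohort significance counts in `glance()` use the
raw values unless adjustment is requested.

## The synthetic-data generator

`simulate_paired_expression()` exists so the full pipeline is testable
without any expression database download. It uses a latent-factor model:
each planted module m has one standard-normal factor z<sub>m</sub> per
sample, shared by both tissues, and member profiles are
L·z<sub>m</sub> + ε with ε ~ N(0, σ²). The loading solves
L²/(L²+σ²) = ρ\*, so the expected cross-tissue correlation between any
tumor member and any stroma member is exactly the target ρ\* — a closed form
a copula construction would not give, which is why the latent-factor model
was chosen. Loadings are symmetric across tissues by default
(`stroma_loading_scale` exposes asymmetry as an extension). Non-member
genes are independent noise.

Survival (`simulate_survival()`) is exponential: the poor-outcome group —
the above-median half of the prognostic module's latent factor — has its
hazard multiplied by `hazard_ratio`. Censoring is independent uniform on
[0, T<sub>max</sub>], with T<sub>max</sub> solved numerically (root of the
closed-form expected censored fraction) to hit the target censoring
fraction; this is simpler than administrative censoring and sufficient for
calibration and power testing.

What the generator deliberately does **not** emulate: probe-level
structure, batch or array effects, heavy-tailed intensity marginals,
correlated background genes, or non-proportional hazards. Tests passing on
this generator show the pipeline's logic and guarantees are correct; they
do not certify performance on real microarray cohorts, where background
correlation structure makes thresholds bite differently.

## Numerical and design choices

* **Degenerate inputs.** Empty graphs mine to empty results; an empty edge
  set after thresholding warns rather than errors; a gene with exactly zero
  mean counts as zero-variation under the CV filter; zero observed events
  give log-rank statistic 0 and p = 1; one-sided/empty member sets are
  density errors.
* **The "< 20% variation" filter** is ambiguous between a coefficient-of-
  variation cut and a variance-quantile cut; both are implemented
  (`mode = "cv"` default, `mode = "quantile"`), and the mode used is part
  of the run configuration.
* **Median matching** between the separately normalized tissues is a pure
  global offset (scale fixed at 1): it aligns the overall medians exactly
  while provably preserving ranks and all linear relationships, and it is
  idempotent.
* **Tolerances.** Densities are recomputable from the graph to 1e−9 (the
  level used by `verify_density_bound()` and the trace-replay tests);
  correlation and density oracles in the test suite agree to 1e−12.
* **K-means restarts** re-seed an emptied cluster with the worst-fit
  sample rather than failing; with K = 2 this occurs only in near-
  degenerate data.

## Problem sizes used in the test suite

The suite exercises: 20×20 random graphs across 200 seeds for the density
guarantee sweep; a planted 15×15 module at ρ\* = 0.8 with 200 samples and
construction threshold 0.5 across 10 seeds for module recovery (Jaccard
≥ 0.8 against ground truth); 1000 null replicates at n = 80 for log-rank
calibration and 50 replicate cohorts at n = 100, hazard ratio 3, 20%
censoring for power; and three planted modules on 60+60 genes for the
merging contract. These sizes were chosen as the smallest at which the
Monte-Carlo checks are stable.

## Known limitations

* The density guarantee bounds d(B) relative to the *seed* weight; it says
  nothing about whether a BiNet is biologically coherent — that remains an
  enrichment/validation question outside this package.
* Greedy growth with single-side termination can miss denser components a
  two-sided or backtracking search would find; the guarantee, not
  optimality, is the contract.
* The merge dendrogram's ordering is a property of this package's
  agglomerative scheme; other density-guaranteed merge procedures can
  produce different trees over the same macro partition.
* Correlation-threshold graph construction inherits all the usual caveats
  of marginal correlation networks (indirect associations, confounding by
  shared factors).
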