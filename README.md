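# binetminer

Dense bipartite sub-network mining for tumor–stroma co-expression analysis.

Tumor cells and the surrounding stroma (the tumor microenvironment)
coordinate their gene expression. Given expression profiles of matched tumor
and stroma tissue from the same specimens, the cross-tissue co-expression
structure can be modeled as a **weighted bipartite graph**: tumor genes on
one side, stroma genes on the other, and an edge of weight
ρ<sub>i,j</sub> wherever the Pearson correlation between tumor gene
*g<sub>i</sub>* and stroma gene *g<sub>j</sub>* across the matched samples
clears a threshold. `binetminer` is for computational biologists who want to
find the densely connected bipartite components (**BiNets**) of such a
graph — candidate co-regulated tumor/stroma gene modules — and test them as
prognostic biomarkers, with a *provable* lower bound on the density of every
reported component.

## The algorithm

For a BiNet *B* with sides of size *a* and *b*, define its density

> d(B) = Σ<sub>e∈E(B)</sub> w(e) / (a·b),

the average weight over all vertex pairs (absent edges count 0), and the
contribution of a candidate vertex *v* as the mean weight of its edges into
the opposite member set. Mining proceeds seed-and-grow:

1. Sort edges by descending weight; let w<sub>max</sub> be the heaviest.
2. Every not-yet-selected edge with weight ≥ β·w<sub>max</sub> seeds a BiNet.
3. Grow by repeatedly taking each side's best-contribution candidate,
   comparing the two, and admitting the winner only if its contribution is at
   least α times the current density, where
   α = 1 − 1/(λ(i+τ+1)), λ = max{1, C/(i+τ+1)²}
   for current side size *i*; growth stops at the first failure.
4. Admitted vertices mark their edges into the current opposite side as
   selected; vertices (genes) may still be shared between BiNets.

The schedule guarantees, for every output BiNet,

> d(B) / w(seed) ≥ F(C, τ) = ((2C−τ−2)/(2C))<sup>2k</sup> · ((√C−τ−1)/(√C−τ))²,
> k = max(0, ⌈√C−τ−1⌉−1),

so with the defaults C = 36, τ = 2, β = 0.7 every BiNet's density is at
least `density_bound(36, 2)` ≈ 0.4475 times its seed-edge weight.

The package implements the whole surrounding pipeline: a synthetic-data
generator (paired-tissue matrices with planted cross-tissue modules and
survival outcomes), median-matched normalization and low-variation
filtering, graph construction, mining, density-thresholded agglomerative
merging of BiNets into macro networks (with a Newick dendrogram), and
survival evaluation (city-block K-means two-group split + log-rank test).

## Worked example

```r
library(binetminer)

sim <- simulate_paired_expression(
  n_tumor_genes = 80, n_stroma_genes = 80, n_samples = 47,
  modules = list(module_spec(12, 12, 0.85), module_spec(8, 8, 0.8)),
  prognostic_module = 1, hazard_ratio = 3, censoring_fraction = 0.2,
  seed = 1
)
paired <- median_match_normalize(paired_expression(sim$tumor, sim$stroma))
graph  <- build_coexpression_graph(paired, min_weight = 0.6)
result <- bcm_mine(graph, bcm_params(C = 36, tau = 2, beta = 0.7))
tidy(result)
#> # A tibble: 2 × 8
#>   binet_id seed_x seed_y seed_weight   n_x   n_y n_genes density
#>      <int> <chr>  <chr>        <dbl> <int> <int>   <int>   <dbl>
#> 1        1 TG0001 SG0009       0.929    12    12      24   0.858
#> 2        2 TG0016 SG0017       0.837     8     8      16   0.767
```

Both planted modules are recovered exactly: BiNet 1 is the 12×12 module
(density 0.858, well above the guaranteed floor 0.4475 × 0.929 = 0.416) and
BiNet 2 the 8×8 one. Merging and survival evaluation continue from there:

```r
kept   <- filter_min_genes(result, min_genes = 10)
macro  <- merge_binets(kept, graph, threshold = 0.3)
tidy(macro)
#> # A tibble: 1 × 5
#>   macro_id n_binets   n_x   n_y density
#>      <int>    <int> <int> <int>   <dbl>
#> 1        1        2    20    20   0.431

cohort <- simulate_survival(sim, seed = 2)
ev <- evaluate_binets(kept, list(main = cohort), n_restarts = 100, seed = 3)
glance(ev)
#> # A tibble: 1 × 5
#>   cohort n_evaluated n_significant n_significant_any alpha
#>   <chr>        <int>         <int>             <int> <dbl>
#> 1 main             2             1                 1  0.05
```

The two BiNets merge into one macro network (their union still has density
0.431 ≥ 0.3), and only the BiNet built on the prognostic module separates
the cohort into groups with significantly different survival (log-rank
p < 0.05) — module 1 carried the hazard signal (hazard ratio 3), module 2
did not. `autoplot()` methods exist for mining results, merges and
evaluations, and `plot_km_curves()` draws the Kaplan–Meier curves of a
split.

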