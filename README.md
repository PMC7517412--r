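# fdnet

Structural covariance network analysis of the cerebral cortex based on the
three-dimensional box-counting **fractal dimension** (FD) of parcellated
regions.

Cortical atrophy changes the shape complexity of gray matter, and FD — the
slope of the box-counting power law — captures that complexity with small
variance and little sex effect, which makes it a useful morphometric marker
for comparing groups (e.g. middle-aged vs elderly cohorts). `fdnet`
implements the full pipeline for two-group FD covariance studies:

1. **Regional FD.** For each region of a rearranged 68-region
   Desikan–Killiany parcellation (frontal 1–28, temporal 29–46,
   parietal 47–60, occipital 61–68; odd = left, even = right), the binary
   gray-matter mask is covered by grids of cubes of edge *r* and the number
   of occupied boxes *N(r)* is counted across scales. FD is the OLS slope of
   `log N(r) = FD · log(1/r) + k`.
2. **Covariance network.** Within a group, each pair of regions is scored by
   the Pearson correlation of their FD values across subjects, giving a
   68 × 68 matrix per group; the 20 % strongest positive coefficients are
   retained as weighted edges (proportional threshold).
3. **Modules and connectivity.** The network is decomposed by weighted
   modularity maximisation,
   `Q = (1/2m) Σ_ij [A_ij − k_i k_j / 2m] δ(c_i, c_j)`,
   with an in-package Louvain-style optimiser. Node roles are summarised by
   the within-module degree z-score `z_i = (k_i − k̄_c) / σ_c` (hubs:
   z ≥ 2.5) and the participation coefficient
   `P_i = 1 − Σ_c (k_ic / k_i)²`, and lobes by intra-/inter-lobe weight
   sums and density-normalised means.
4. **Group comparison.** Per-region Welch t-tests with Benjamini–Hochberg
   FDR over the 68 regions; whole-network properties (which yield a single
   value per group) are compared through a sex-balanced permutation scheme:
   25 women and 25 men drawn from each group, pooled and reassigned into two
   sex-balanced randomized groups, the property recomputed per randomized
   group, 1000 times; the observed difference is judged against the null's
   95th percentile, with an add-one empirical p-value and a permuted-sample
   t-test reported alongside.

Because subject-level scans for such studies are rarely distributed, the
package also ships generators for everything needed to exercise and validate
the pipeline: fractal phantoms with known analytic dimension (cube, slab,
line, Menger sponge, Cantor dust) and synthetic two-group cohorts with
planted covariance blocks, planted regional group effects on the scale of
published two-group differences, and balanced sex labels.

## Worked example

```r
library(fdnet)

# FD of a level-2 Menger sponge: exact triadic power law
sponge <- make_phantom("menger_sponge", 2)
estimate_fd(box_counts(sponge, default_sizes(sponge, base = 3)))
#> <fd_estimate> fd = 2.7268 (R^2 = 1.0000, 3 scales)

# Synthetic two-group cohort (100 + 100 subjects, 5 planted blocks)
cohort <- make_cohort(cohort_config(n_per_group = 100, seed = 7))
net <- threshold_proportional(correlation_matrix(cohort, "middle"), 0.20)
net
#> <brain_network> 68 nodes, 456 edges (proportion 0.20, requested 456)

part <- detect_modules(net, seed = 7, n_restarts = 50)
part
#> <module_partition> 5 modules (sizes 22/14/13/11/8), Q = 0.6928
adjusted_rand_index(part$assignment,
                    planted_truth(cohort_config(n_per_group = 100, seed = 7))$partition)
#> [1] 1

# Node roles, summarised per lobe
z <- within_module_z(net, part)
node_metric_report(z)
#>        lobe   total    left   right
#> 1   frontal  0.1222  0.1850  0.0595
#> 2  temporal  0.0856 -0.2190  0.3901
#> 3  parietal -0.0116 -0.0625  0.0392
#> 4 occipital -0.5999 -0.6415 -0.5584

# Regional two-group comparison (BH-FDR over 68 regions)
tests <- regional_fd_ttests(cohort)
tests[tests$q_value < 0.05, c("roi", "label", "mean_a", "mean_b", "q_value", "direction")]
#>  roi    label mean_a mean_b q_value direction
#>    1  CACg(L)  2.122  2.065 0.00483  decrease
#>   67 PerCa(L)  2.054  2.102 0.02331  increase
```

The sponge estimate equals `log 20 / log 3 ≈ 2.7268` because each triadic
subdivision keeps 20 of 27 cells, so the box counts `{400, 20, 1}` at sizes
`{1, 3, 9}` lie exactly on the power law. The detected partition reproduces
the five planted covariance blocks exactly (adjusted Rand index 1), and Q is
recomputed from the partition, not carried over from the optimiser. The
regional table flags the two regions with the largest planted shifts at this
sample size; q-values are BH-adjusted over all 68 tests.

A thin command-line wrapper over the same functions is installed at
`inst/cli/fdnet` (subcommands `simulate`, `fd`, `net`, `modules`, `metrics`,
`compare`, `report`), e.g.:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "fdnet", package = "fdnet"))')" \
  simulate --out runs/demo --seed 4 --n-per-group 100
```

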