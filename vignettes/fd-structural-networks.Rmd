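---
title: "Fractal-dimension structural covariance networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal-dimension structural covariance networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures implemented in `fdnet`,
the choices made where the methodology is genuinely open, and what the
synthetic validation data can and cannot show about real cohorts.

## The box-counting fractal dimension

A voxelised object with fractal scaling obeys the power law
$N(r) \propto r^{-\mathrm{FD}}$, where $N(r)$ is the number of axis-aligned
cubes of edge $r$ (in voxel units) containing at least one occupied voxel.
`estimate_fd()` fits $\log N(r) = \mathrm{FD}\cdot\log(1/r) + k$ by ordinary
least squares and reports the slope, intercept, and $R^2$. Natural
logarithms are used; the base cancels in the slope.

Three numerical choices are not dictated by the power law itself and are
fixed as follows:

* **Size progression.** Geometric, $r = b^0, b^1, \dots, b^K$ with
  $b^K \le$ the largest bounding-box extent, base $b = 2$ by default and
  $b = 3$ selectable (`default_sizes()`). Dyadic sizes are standard
  practice and exact on dyadic phantoms; triadic sizes recover the Menger
  sponge and Cantor dust exactly, because then every count lies on the
  analytic power law (the level-2 sponge gives $\{400, 20, 1\}$ at
  $\{1,3,9\}$ and a slope of exactly $\log 20/\log 3 \approx 2.7268$).
  At least three scales are required; `fd_per_roi()` tolerates two for very
  small regions and returns `NA` below that.
* **Grid anchoring.** The counting grid is anchored at the minimum corner of
  the mask's bounding box, and the mask is cropped to that bounding box
  first, so padding or translation inside a larger volume cannot change the
  counts (the translation test requires exact equality). No multi-offset
  minimisation is performed; with it, counts could only decrease, typically
  lowering FD slightly near the resolution limit.
* **Degenerate inputs.** Empty masks are a domain error. A curve with
  constant counts (single voxel) has slope 0 and is reported with
  $R^2 = 1$, since the flat line fits it exactly. Regions with fewer than
  `min_voxels = 8` occupied voxels yield `NA`: a two- or three-point
  regression on a handful of voxels says nothing about shape complexity.
  `NA` regions propagate to pairwise-complete correlations downstream.

Counting is performed in voxel units; anisotropic voxel sizes are recorded
but ignored, which is a known limitation shared with most box-counting
implementations. FD is computed per region on whatever tissue labels the
input volume carries; whether that is gray matter only or gray plus white
matter is a property of the upstream segmentation, not of this package.

## The covariance network

"Structural covariance" is implemented as the Pearson product–moment
correlation of regional FD across the subjects of one group — the standard
construction for morphometric covariance networks. Missing FD values are
handled pairwise; constant columns produce undefined correlations that are
recorded as 0 with a counted warning.

The proportional threshold (`threshold_proportional()`, default 0.20)
retains the $\lceil p\,E\rceil$ largest positive coefficients among the
$E = n(n-1)/2$ unique pairs, keeping their weights; the diagonal and all
negative correlations are removed. For 68 nodes at $p=0.2$ that is at most
$\lceil 0.2 \cdot 2278 \rceil = 456$ edges. Two deterministic conventions:
the requested count is taken over *all* unique pairs, not only positive
ones, so the edge budget does not depend on the sign pattern; and entries
tied exactly at the cutoff are all kept (order-independence), with the
realized count reported. The retained network stays weighted because the
modularity definition sums coefficient weights.

## Modules, node roles, lobe connectivity

Modularity is the weighted form
$Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \frac{k_i k_j}{2m}\right]
\delta(c_i, c_j)$ with $k_i$ the node strength and $m$ half the total
weight. Module detection is a greedy multilevel (Louvain-style) maximisation
implemented in the package: the local-moving sweep (in C++) visits nodes in
a seed-shuffled order and moves a node when the modularity gain exceeds
$10^{-12}$, levels aggregate until no merge occurs, and the best of
`n_restarts` runs by $Q$ is kept (first encountered among exact ties). If no
partition reaches $Q \ge 0$ the all-in-one partition ($Q = 0$) is returned,
so the result is never worse than no partition at all. Module ids are
renumbered by decreasing size (ties by smallest contained region index), so
module 1 is always the largest. Tests verify the implementation against a
brute-force evaluation of the definition, against `igraph::modularity`, and
against exhaustive enumeration of all partitions on networks of up to 7
nodes.

Node roles use the within-module degree z-score
$z_i = (k_i - \bar k_{c_i})/\sigma_{c_i}$ and the participation coefficient
$P_i = 1 - \sum_c (k_{ic}/k_i)^2$. Choices:

* **Population SD** (divide by module size) in $z$; modules with zero SD —
  including singletons — give $z = 0$ rather than undefined values.
* **Weighted by default.** The modularity definition sums weights, but the
  z/P formulas are verbally defined over edge *numbers* in parts of the
  literature; both modes are implemented (`weighted = FALSE` counts edges)
  and the weighted mode is the default. Both are scale-invariant under
  uniform weight scaling, so the choice of correlation units cannot leak in.
* **Hubs** are nodes with $z \ge 2.5$, the established convention for
  within-module degree; the threshold is a parameter because no universal
  value exists.
* Isolated nodes take $P = 0$ by convention.

Lobe-level summaries come in two families: means of node metrics over a
lobe's regions (`lobe_mean()`, `node_metric_report()`), and aggregate edge
weights (`lobe_weight_connectivity()`): intra-lobe = weights of edges with
both endpoints in the lobe (per hemisphere or jointly), inter-lobe = weights
of edges with exactly one endpoint in the lobe. Published two-group tables
of this kind print values around 0.3–0.7, which raw 456-edge weight sums
cannot produce, so the exact normalisation behind such tables is not
derivable from their verbal "sum of connectional weights" definition; the
package therefore reports **both** the raw sum and the density-normalised
mean (sum divided by eligible pairs), and the packaged reference tables are
used for ratio arithmetic directly rather than being regenerated. The
conservation identity (intra sums over the four lobes plus all lobe-crossing
weights equals total strength) is checked by brute force in the tests.

## Two-group statistics

Regional comparisons are two-tailed Welch t-tests per region (the pooled
test is available via `var_equal`) with Benjamini–Hochberg q-values over the
68 regions — "FDR correction" without further qualification is taken to
mean BH. Degenerate zero-variance regions give $p = 1$ (equal means) or a
flagged $p = 0$ (unequal means).

Whole-network properties yield one value per group, so they are compared
with a sex-balanced permutation scheme (`permutation_compare()`): per
permutation, 25 women and 25 men are drawn from each group, the pooled 100
subjects are reassigned into two randomized 50-subject groups that each keep
the 25F + 25M balance (the only split consistent with sex-balanced
randomized groups of 50), each randomized group's network is rebuilt from
scratch, and the property difference is recorded. Because the literature
describes both a 95th-percentile criterion and a one-tailed t-test on
permuted parameter sets without disambiguating them, the result carries
three labelled outputs: the add-one empirical p-value
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(B+1)$ (never exactly 0), the
95th-percentile decision, and a Welch t-test on the two randomized groups'
permuted samples. Everything is seed-deterministic; per-permutation module
detection seeds are drawn from the same stream.

One property of this design is worth stating plainly: the observed
difference comes from full-size groups (here $n = 100$ per group) while the
null differences come from 50-subject randomized groups, whose property
estimates are noisier. The null spread is therefore wider than the observed
difference's sampling variation, and the 95th-percentile criterion is
*conservative* — on null synthetic cohorts the measured rejection rate
(`permutation_null_rejection_rate` in the acceptance output) sits at or
below the nominal 5%.

## The synthetic-data generator

`make_cohort()` draws each group from a 68-dimensional multivariate normal
with a compound-symmetric block correlation structure: correlation 0.5
inside each of five planted blocks and 0.1 between blocks. The blocks are
the five-module partition of the packaged middle-aged reference network
(sizes 22/14/13/11/8), so the planted optimum matches an empirically
observed modular layout. Baseline means are the reference lobe-by-hemisphere
FD means (about 2.0–2.45), overridden with region-specific published means
for the 16 regions that have them; the per-region, across-subject SD is
0.10, the printed scale of the reference lobe table. Group B's means are
shifted by the 16 printed group differences (e.g. left pericalcarine
+0.0519, most others negative), sex labels are balanced 50/50, and the
implied correlation matrix is validated to be positive semi-definite at
configuration time — invalid configurations fail loudly with the offending
eigenvalue rather than being silently repaired.

What this emulates: the sampling noise of per-region FD means, block-wise
covariance structure, balanced sex composition, and group effects of
published magnitude. What it does not emulate: non-Gaussian and bounded FD
distributions, spatially smooth correlation structure (real neighbouring
regions correlate more), heteroscedastic per-region SDs, age trends within
groups, and any form of measurement artefact. Passing the recovery tests
therefore shows the pipeline is correct and well calibrated, not that real
cohorts of this size would yield the same power.

Two calibration outcomes computed by the acceptance script deserve honest
discussion:

* **Regional-test power.** With the printed group differences (0.008–0.052
  FD) against the configured SD of 0.10, per-region effect sizes are
  $d \approx 0.08$–$0.52$, and the measured recovery at $q < 0.05$
  (`regional_effect_recovery_rate`) is about 0.11 — not the near-complete
  recovery one might expect from a table of "significant regions". The
  tension is in the source scale itself: a pooled lobe-level SD of 0.10 is
  not the per-region SD (published regional p-values of 0.005–0.048 at
  $n = 100$ imply per-region SDs nearer 0.03–0.06). The generator keeps the
  stated defaults rather than tuning them; users simulating power for their
  own designs should set `roi_sd` from their own per-region estimates (at
  `roi_sd = 0.04` the same deltas are recovered at about half the regions,
  as the sensitivity test in the suite computes).
* **Permutation power for Q.** Raising one group's within-block correlation
  by 0.15 (0.65 vs 0.5) barely moves the modularity of the thresholded
  network: the 20% threshold keeps a nearly identical, almost entirely
  within-block edge set in both conditions, and $Q$ is invariant to uniform
  weight scaling, so the measured detection rate
  (`permutation_effect_detection_rate`) is 0. A modular-strength contrast
  of this form is simply not expressed in $Q$ after proportional
  thresholding; contrasts that change the *topology* of the retained edge
  set (e.g. weakening block structure toward the between-block level, or
  lobe-specific rewiring) are what this statistic can detect.

## Problem sizes and defaults

| Parameter | Default | Where | Rationale |
|---|---|---|---|
| box-size base | 2 (3 selectable) | `default_sizes` | dyadic standard; triadic exact on triadic phantoms |
| `min_voxels` | 8 | `fd_per_roi` | below this a log–log regression is meaningless |
| threshold proportion | 0.20 | `threshold_proportional` | retains the strongest fifth of coefficients; 456 edges at 68 nodes |
| detection restarts | 100 (20 inside permutations) | `detect_modules` | 68-node networks saturate well below this |
| hub threshold | $z \ge 2.5$ | `classify_hubs` | established convention |
| permutations | 1000 (200 in calibration runs) | `permutation_compare` | add-one p resolution 1/1001; calibration runs use 200 × 20 seeds |
| cohort size | 100 per group, 50/50 F/M | `cohort_config` | reference study conditions |

Calibration simulations in the tests and acceptance script use 10–20 seeds
with 200 permutations each; these sizes give binomial standard errors of
about 5 percentage points on the reported rates, which is why the null
rejection rate is judged within a ±0.10 band around the nominal 5%.

## Known limitations

* FD ignores voxel anisotropy and is computed on native-grid masks; no
  surface-based FD, multifractal spectra, or lacunarity.
* No covariate residualisation (age, sex) before correlation; the sex
  balance of the permutation scheme is the only sex control.
* One network per group by construction: no subject-level network variance,
  hence no parametric network comparison.
* Exact replication of published module memberships is not a meaningful
  contract — they derive from cohort data that is not distributed and from
  an unnamed optimiser; the packaged reference partitions are used as
  fixtures and as the planted-block default, not as an acceptance target.
* The alternative hypotheses the permutation test can detect are limited to
  effects that survive proportional thresholding, as discussed above.
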