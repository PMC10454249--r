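---
title: "Methods: group-level structural covariance networks in scnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-level structural covariance networks in scnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

# The model and its assumptions

`scnet` analyzes *structural covariance*: the tendency of regional brain
volumes to co-vary across subjects within a group. Because the
correlation is computed across subjects, the network exists only at the
group level — there is no per-subject network, and consequently no
individual-level cutoff or prediction; group comparison is done by
permutation of subject labels.

The pipeline assumes:

* **Linear nuisance structure.** Age and sex affect each region's volume
  additively and linearly. Residualizing on `[1, age, sex]` by OLS is
  exact under that assumption; curvature in the age effect or
  age-by-group interactions are *not* removed and would leak into the
  edges.
* **Pearson edges.** Covariance is summarized by the Pearson correlation
  of residuals. Edges are therefore scale-invariant per region (z-scoring
  volumes first would change nothing) but sensitive to heavy-tailed
  outliers.
* **Non-negative connectivity.** Negative residual correlations are set
  to zero before graph analysis. This is the standard convention for
  covariance networks, where measure definitions require non-negative
  weights; it also means "anticorrelated" and "uncorrelated" region pairs
  are indistinguishable downstream.
* **Adjusted correlation, not full partial correlation.** "Controlling
  for age and sex" means correlating covariate residuals. Partialing out
  all other regions as well is deliberately not offered: with dozens to
  hundreds of regions and group sizes in the tens, that inverse
  covariance is ill-posed.

# Graph measures and their conventions

All measures operate on the weighted, undirected, zero-diagonal matrix
`w` with entries in `[0, 1]`.

* **Weight-to-length mapping.** Shortest paths use edge length `1/w`
  (default), so a correlation of 1 is one unit of distance. This is the
  dominant convention for correlation-weighted brain networks. `1 - w`
  and `-log w` are available via `convention =` but are not the tested
  default; under `1 - w`, unit-weight edges have zero length and
  efficiencies diverge, which is the user's responsibility.
* **Global efficiency** is the mean of `1/d(i, j)` over ordered pairs,
  with unreachable pairs contributing 0.
* **Local efficiency** of a node is the global efficiency of the
  subnetwork induced on its neighbors, *keeping original weights* (no
  per-subgraph renormalization); nodes with fewer than two neighbors
  contribute 0, and the network value is the mean over all nodes.
* **Clustering** is the Onnela geometric-mean form with max-weight
  normalization, so it is invariant under uniform weight scaling; nodes
  of degree < 2 contribute 0; an all-zero network is defined to have
  clustering 0 (with a warning).
* **Characteristic path length** averages finite distances over ordered
  pairs. Unreachable pairs are *excluded* (their count is attached as an
  attribute and messaged), rather than substituted with N or infinity:
  covariance networks are near-complete, so disconnection is rare and
  accidental, and exclusion keeps the statistic finite and comparable.
  Only a fully disconnected network returns `Inf`.
* **Assortativity** correlates endpoint *binary* degrees over the
  directed edge list (both orientations of each positive edge). Weighted
  endpoint strength is available behind `weighted = TRUE` but is not the
  default. When endpoint degrees have zero variance (regular graphs,
  including the complete graph) the coefficient is undefined and is
  reported as `NA` — never coerced to 0. The same `NA` discipline
  propagates into permutation results: a measure undefined in the
  observed networks, or defined in too few permutations to form a null
  distribution, yields `NA` p-value and interval rather than aborting
  the comparison.
* **Average degree** is reported alongside the six classical summary
  measures because group differences in the number of surviving
  (positive) edges are informative on their own; `include_average_degree
  = FALSE` restores the six-measure family.

The compiled core (`src/metrics.cpp`) implements Floyd–Warshall
all-pairs shortest paths and the neighbor-subgraph efficiency loop; the
test suite checks every measure against two independent routes —
exhaustive simple-path enumeration in plain R on all graphs with up to 7
nodes, and `igraph` distances on larger random graphs — at tolerance
1e-9.

# Inference

Between-group differences of group-level statistics have no subject-level
sampling distribution, so inference is by exchangeability: pooling both
groups and relabeling subjects into pseudo-groups of the original sizes,
then recomputing residualization, network and measures *within each
pseudo-group*. Redoing the residualization per permutation matters — the
statistic must be recomputed under relabeling exactly as it was observed.

* p-values are two-sided with the add-one estimator
  `(#{|null| ≥ |obs|} + 1)/(m + 1)`, which cannot be 0 and is valid under
  exchangeability. With 1000 permutations the smallest attainable value
  is about 0.001.
* The reported interval is the central percentile interval of the *null*
  permutation distribution of differences — a significance yardstick
  ("what difference magnitudes does label noise produce"), not a
  bootstrap interval around the estimate. It need not bracket the
  observed difference, and users are told so in the documentation.
* FDR adjustment is standard Benjamini–Hochberg step-up, applied across
  the measure family of one network comparison (7 measures by default).
  The implementation is checked against `stats::p.adjust` and against a
  brute-force min-over-tails evaluation. No Bonferroni variant is
  offered.
* Degenerate permutations (a pseudo-group with constant age) are redrawn
  with a logged count, up to 10 times the requested number of
  permutations, so small-cohort runs survive.

# The synthetic generator: what a green test establishes

`generate_cohort()` draws volumes as
`mean + age_effect·(age − age_mean) + sex_effect·sex + noise_sd ⊙ z`,
with `z` multivariate normal under the group's target correlation, ages
truncated-normal on [40, 95] (resampling) and sex Bernoulli. This is
*exactly* the statistical world the method assumes — linear confounds,
Gaussian noise, a fixed per-group correlation — which is what makes
parameter recovery a meaningful test: the estimated edges must converge
to `max(0, target)` and they do (tested at n = 2000 within 0.05).

Deliberately absent from the generator, and therefore *not* established
by green tests: measurement/segmentation error correlated across regions,
non-Gaussian and heteroscedastic volume noise, nonlinear age effects,
site/scanner batch structure, and any relation between covariates and
group beyond what the user specifies. Defaults chosen once as realistic
for volumetry: mean volumes 5000 mm³ (cortical-scale) with noise SD
500 mm³ (10% CV), age slope −15 mm³/year (slow atrophy), male offset
+300 mm³; the demo's thalamic block scales these down (200 / 25 /
−0.8 / +10) to nucleus-sized volumes. Demographics default to age
69.9 ± 11.9 years and 47% male, matching a typical late-onset dementia
cohort.

The bundled demo fixes group sizes at 25 / 56 / 45 and gives the
epilepsy group a covariance template distinct from the other groups in
both blocks — weaker diffuse global covariance (uniform 0.25 vs modular
0.45–0.6) and *stronger* uniform thalamic covariance (0.55 vs modular
0.4–0.5) — so the expected direction of every demo contrast is known by
construction.

Correlation templates are PSD by construction (`uniform`, `modular` as
non-negative combinations of PSD parts) or by projection
(`smallworld-like`: eigenvalue clipping then unit-diagonal rescaling, a
congruence that preserves PSD). The eigen-factor sampler handles
rank-deficient targets.

# Numerical choices and degenerate inputs

* OLS via QR (`qr.resid`), residual orthogonality to the design checked
  at 1e-6 relative; a zero-variance volume column gives all-zero
  residuals and a named warning, not an error, so degraded real data
  still run.
* Exact symmetry of weight matrices is enforced by mirroring the upper
  triangle (floating-point `cor` output is symmetrized, never trusted).
* Groups need at least 4 subjects for residualization (intercept + age +
  sex + 1 error degree of freedom); pure IO accepts smaller tables.
* Sex is accepted as `{0, 1}` or `{F, M}` and normalized; any other
  coding is an error, never a guess. Region columns are matched by exact
  name.
* Result writers render doubles at 15 significant digits so that reruns
  under the same seed are byte-identical; the run log is the one file
  that records machine-specific paths.
* Per-comparison permutation seeds are derived as `seed + task_index`
  over the network × comparison grid: deterministic end to end, distinct
  streams per table.
* The null-data calibration test uses independent regions as the shared
  generative spec. Under strong uniform correlation the zero-clipped
  network is complete and regular, making assortativity undefined in
  nearly every permutation; the independent-regions null keeps all seven
  rejection rates measurable. Measured type-I error at α = 0.05 lies in
  [0.02, 0.08] for every measure (500 replicates, 200 permutations).

# Known limitations

* No nodal (per-region) statistics, no thresholded/binarized density
  sweeps, no modularity/betweenness/small-world index: only the global
  summary measures.
* The percentile-of-null interval is unconventional if read as a
  confidence interval for the difference; it is kept because it is the
  natural permutation companion of the p-value, and it is clearly
  labeled.
* The default region lists are configurable stand-ins with
  FreeSurfer-style names, not a canonical atlas definition; no fuzzy
  label matching is attempted.
* Runtime scales as O(N³) per permutation for path-based measures plus
  O(N · N³) for local efficiency; the compiled core keeps an 82-node,
  200-permutation comparison at roughly half a minute on one CPU, but
  very large node sets (500+) would need a different algorithmic
  approach.
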