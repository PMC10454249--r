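# scnet — structural covariance networks of regional brain volumes

`scnet` is an R package for **group-level structural covariance network
analysis**: it turns a table of per-subject regional brain volumes (for
example FreeSurfer cortical, subcortical and thalamic-nucleus volumes in
mm³) into weighted covariance networks per group, summarizes each network
with graph-theory measures, and compares groups with label-permutation
tests and Benjamini–Hochberg false discovery rate (FDR) correction. It is
aimed at neuroimaging groups who have volumetric exports and group labels
(e.g. patients who did or did not develop epilepsy after an Alzheimer
disease diagnosis, and healthy controls) and want a reproducible,
scriptable version of the standard covariance-network workflow.

## The method

A structural covariance network exists **per group**, not per subject.
For one group with subjects *s* = 1…n and regions *i* = 1…N:

1. **Residualize.** Each region's volumes are regressed on `[1, age, sex]`
   by ordinary least squares; the residuals `e_i` carry the
   covariate-adjusted signal.
2. **Correlate.** Edge weights are Pearson correlations of residuals,
   with negative coefficients set to zero:
   `w_ij = max(0, cor(e_i, e_j))`, `w_ii = 0`. This is the
   covariate-adjusted correlation convention of group-level covariance
   tools (not partial correlation given all other regions, which is
   ill-posed for N ≫ n).
3. **Measure.** With edge lengths `1/w` (strong correlation = short
   path), the package computes: global efficiency
   `E = mean_{i≠j} 1/d(i,j)`, local efficiency (mean over nodes of the
   global efficiency of the neighbor-induced subgraph), mean weighted
   clustering coefficient (Onnela geometric-mean form,
   `C_i = Σ_{j,h}(ŵ_ij ŵ_ih ŵ_jh)^{1/3} / (k_i(k_i−1))` with
   `ŵ = w/max(w)`), characteristic path length (mean finite `d(i,j)`),
   average strength, average degree, and the degree assortativity
   coefficient (undefined on regular graphs, reported as `NA`).
4. **Compare.** Two groups are compared by pooling subjects and randomly
   relabeling them into pseudo-groups of the original sizes; the *whole*
   pipeline is recomputed per permutation (1000 by default). Two-sided
   p-values use the add-one estimator `(b+1)/(m+1)`; each measure also
   gets the central 95% percentile interval of the *null* difference
   distribution (which need not bracket the observed difference), and
   p-values are BH-adjusted across the measure family of one comparison.

A synthetic cohort generator with known covariate effects and prescribed
per-group correlation structure makes every stage testable without
patient data.

## Worked example

The bundled demo generates a synthetic cohort emulating a three-group
volumetric study (25 AD-with-epilepsy, 56 AD-without-epilepsy, 45 healthy
controls; age 69.9 ± 11.9 years, 47% male; 82 global regions + 50
thalamic nuclei), builds both networks for every group and runs all three
pairwise comparisons at 200 permutations:

```r
library(scnet)
res <- demo_pipeline(seed = 7, output_dir = "demo_out", n_permutations = 200)
print(res$thalamic$AD_no_epilepsy_vs_AD_epilepsy, digits = 3)
```

```
                      measure group_a group_b difference ci_lower ci_upper
1           global_efficiency   0.307  0.4530     0.1464  -0.0564   0.1365
2            local_efficiency   0.316  0.4541     0.1379  -0.0422   0.1354
3 mean_clustering_coefficient   0.330  0.5158     0.1858  -0.1516   0.1300
4  characteristic_path_length   3.960  2.3915    -1.5681  -1.2537   0.7605
5            average_strength  12.411 21.4389     9.0282  -5.4817   6.9725
6              average_degree  41.840 48.6800     6.8400 -11.4660   3.7710
7     assortative_coefficient  -0.101 -0.0551     0.0459  -0.0391   0.0558
  p_value adjusted_p_value significant
1 0.01493           0.0261        TRUE
2 0.02488           0.0348        TRUE
3 0.01493           0.0261        TRUE
4 0.00995           0.0261        TRUE
5 0.00995           0.0261        TRUE
6 0.19900           0.1990       FALSE
7 0.08000           0.0933       FALSE
```

Reading the table: the demo's epilepsy group is generated with *stronger*
uniform thalamic covariance than the non-epilepsy group, and the pipeline
recovers exactly that — higher efficiency, clustering and strength,
shorter characteristic path length (group_b − group_a differences, each
with its permutation-null 95% interval, raw permutation p and BH-adjusted
p across the 7-measure family). `demo_out/` additionally contains the
cohort CSV, per-group connectivity matrices (labeled square TSV), a
measures table and one comparison TSV per (network, contrast), plus a run
log; reruns with the same seed are byte-identical.

Analyzing your own data is the same three calls without the generator:

```r
coh <- read_cohort("volumes.csv")          # subject_id,group,age,sex,R1,...
net <- group_network(coh, "patients")      # one group's covariance network
res <- compare_groups(cohort_subset(coh, group = "controls"),
                      cohort_subset(coh, group = "patients"),
                      permutation_config(n_permutations = 1000, seed = 1))
```

A command-line interface wraps the same steps
(`generate` / `network` / `measures` / `compare` / `demo`), e.g.
`Rscript inst/cli/scnet demo --seed 7 --out demo_out --permutations 200`.

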