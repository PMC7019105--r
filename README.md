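# scnormbench

Normalization is the first consequential modelling decision in a
single-cell RNA-seq analysis: per-cell counts are distorted by sequencing
depth, capture efficiency and amplification bias, and different correction
strategies make different assumptions about where that distortion lives.
`scnormbench` implements seven normalization methods designed for
single-cell data behind one matrix-in/matrix-out interface, a
negative-binomial count simulator with full ground-truth tracking, and an
evaluation harness that scores each method by how well the normalized data
supports cell-group classification. It is aimed at methodologists and
analysts who want to compare normalization strategies under controlled
conditions before committing to one.

## The methods

For counts `X[i, j]` (gene `i`, cell `j`):

| method | idea | spike-ins |
|---|---|---|
| `normalize_simple()` | `Y = ln(X * 10^4 / colsum + 1)` | no |
| `normalize_samstrt()` | depth from spike-in totals (vs. their geometric mean), Poisson resampling | required |
| `fit_basics()` + `normalize_basics()` | hierarchical Bayes: spikes `Poisson(nu_j mu_i)`, biology `NB(1/delta_i, phi_j nu_j mu_i)`, `nu_j ~ Gamma(1/theta, 1/(s_j theta))`; MCMC; `Y = X / (phi_j nu_j)` | required |
| `normalize_grm()` | per cell, gamma regression of log spike-in concentration on log FPKM, polynomial degree 1–4; genes mapped to predicted log concentration | required |
| `normalize_scran()` | ring pools of cells, robust pool factors `median_i V_ik / U_i`, least-squares deconvolution to per-cell size factors | no |
| `normalize_scnorm()` | quantile regression of log expression on log depth; K slope-matched gene groups, grown until all residual slope modes are within 0.1 | no |
| `normalize_linnorm()` | relative scale `R = X/colsum`, `G = ln(lambda R)`; per-cell line anchored on low-variance "stable" genes, strength `c = 0.5` | no |

Everything returns a `normalized_matrix` (values, scale, size factors,
gene bookkeeping); model-based methods also return fit objects with
broom-style `tidy()`/`glance()` methods. `simulate_counts()` /
`simulate_experiment()` generate two-group NB counts with known per-gene
means and overdispersions, per-cell scaling factors, an injected fold
change in a random gene subset, and a spike-in panel with Poisson-Gamma
capture noise. `benchmark_run()` ties it together: simulate (or load) →
clean → normalize with every method → PCA → repeated stratified KNN
scored by Cohen's kappa. The methods vignette
(`vignettes/normalization-methods.Rmd`) documents every model and design
choice.

## Worked example

```r
library(scnormbench)

sim <- simulate_experiment(n_cells_per_group = 12, n_genes = 2000,
                           n_de = 200, fold_change = 5, seed = 42)
sim$counts
#> <count_matrix> 2024 genes x 24 cells (24 spike-in rows)
#>   conditions: group1=12, group2=12
#>   gene lengths: present

cm <- clean_counts(sim$counts, min_cell_total = 1000)
report <- benchmark_run(list(input = cm, spikein = sim$spike_ref,
                             clean = list(enabled = FALSE),
                             basics = list(n_iter = 1500, burn_in = 500,
                                           thin = 5),
                             n_repeats = 50, seed = 42))
report
#> <evaluation_report> 50 KNN repeats (k=5)
#> # A tibble: 8 × 5
#>   method  median_kappa mean_kappa sd_kappa n_repeats
#>   <chr>          <dbl>      <dbl>    <dbl>     <int>
#> 1 basics          1         1       0             50
#> 2 linnorm         1         1       0             50
#> 3 samstrt         1         0.905   0.195         50
#> 4 scnorm          1         0.99    0.0707        50
#> 5 scran           1         1       0             50
#> 6 simple          1         1       0             50
#> 7 grm             0.75      0.73    0.247         50
#> 8 raw             0.75      0.715   0.247         50
```

Kappa is chance-corrected agreement between true and KNN-predicted cell
groups on held-out cells (1 = perfect, 0 = chance). On this 5-fold-change
simulation the deconvolution, Bayesian, stable-gene, quantile and simple
methods separate the groups essentially perfectly in every split, the
spike-in-only depth correction is less stable, and per-cell gamma
regression — which never shares information across cells — does no better
than raw counts. `autoplot(report)` draws the kappa distributions;
`tidy(report)` returns the per-repeat samples.

A command-line wrapper covers the same workflow from a shell
(`inst/cli/scnormbench`): `simulate`, `normalize`, `evaluate` and
`benchmark` subcommands, each writing its outputs plus a seeded JSON run
manifest.

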