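# ternactive

Ternary transcriptional state calling and per-cell coactivation networks
for single-cell RNA-seq.

## The problem

A gene's expression across single cells is not one number but one of three
states: **no expression** (zero counts), **low expression**, and **high
expression** (transcriptional bursting). Thresholding or Gaussian mixtures
handle this poorly because the non-zero low mode is skewed and non-negative.
ternactive is for analysts who want per-gene, per-cell state calls that are
comparable *across datasets* — and who then want to ask which genes switch
state with cell maturity, and how each single cell's coactivation structure
is organized.

## The model

Counts are placed on the shifted-log CPM scale,
`y_ij = log2(1 + 1e6 * r_ij / sum_k r_kj)`, and for each gene the non-zero
values `x_1..x_n` are fit with a **gamma–normal mixture**

```
f(x) = (1 - ρ) Gamma(x; α, β) + ρ Normal(x; μ, σ²)
```

by EM: Bernoulli(0.5)-seeded memberships, posterior
`z_i = ρ f_N(x_i) / (ρ f_N(x_i) + (1-ρ) f_G(x_i))` in the E-step, weighted
closed-form updates in the M-step with the gamma shape solved through the
inverse digamma function. A cell is called **high** when `z_i ≥ 0.5`. The
result is a ternary matrix (0 none / 1 low / 2 high, NA unfittable); sparse
genes are rescued by pooling with ten random context genes, ten times, with
a majority vote (ties to the smaller call).

Downstream: ternary → binary activity (2 → 1); mature/immature cell groups
from two anchor markers (OMP/GAP43 by default, active for exactly one);
genome-wide Fisher's exact tests with Bonferroni control for
maturity-associated genes; per-cell coactivation networks where edges seen
in more than 1% of cells are removed, scored by Freeman degree
centralization `C = Σ(d_max − d_i) / ((N−1)(N−2))` and compared between
groups with a t-test across a 0.5–5% prevalence sweep. A seeded synthetic
generator with complete ground truth (mixture parameters, planted markers,
planted star/dense network topologies) backs every stage's tests.

## Worked example

```r
library(ternactive)

# 500 genes x 120 cells with 20 planted maturity markers (60/60 cell split)
sim <- generate(synthetic_spec(marker_plan = marker_plan(), seed = 1))
res <- run_pipeline(run_config(output_dir = tempfile(), seed = 1),
                    counts = sim$counts)
res
#> ternactive pipeline result
#>   501 genes x 120 cells | 59 mature, 60 immature, 1 excluded cells
#>   marker scan: 499 genes tested, 20 significant
```

The pipeline transformed counts, fit ~500 per-gene mixtures, called the
maturity groups from the anchors (59 + 60 cells; one cell's anchor call was
ambiguous and was excluded), and flagged exactly the 20 planted markers at
Bonferroni-corrected p < 0.01 — `dplyr::filter(res$scan, significant)`
lists them with their 2×2 counts, odds ratios and directions, e.g. gene
G0010 active in 49/59 mature vs 3/60 immature cells (mature-associated).

Planted hub-partner vs densely connected cells are separated by network
centralization:

```r
na  <- generate_network_activity(network_plan(), seed = 1)
cmp <- compare_group_centralization(na$binary, na$groups)
cmp[, c("threshold", "mean_mature", "mean_immature", "p_value")]
#>   threshold mean_mature mean_immature  p_value
#> 1     0.005       0.952       0.161   1.49e-65
#> 2     0.01        0.952       0.0408  6.05e-59
#> 3     0.02        0.952       0.00486 9.43e-54
#> 4     0.03        0.952       0       4.61e-53
#> 5     0.04        0.952       0       4.61e-53
#> 6     0.05        0.952       0       4.61e-53
```

Star-like cells sit near the centralization maximum of 1, dense cells near
0, at every edge-prevalence threshold in the sweep — the hub-partner
topology contrast survives the uniqueness filter's tuning.
`plot_centralization(build_cell_networks(na$binary, groups = na$groups))`
draws the violin plot.

A command-line wrapper lives at `inst/cli/ternactive.R`
(`simulate` and `all` subcommands); the methods vignette
(`vignettes/ternary-states-and-coactivation.Rmd`) documents the model,
the numerical choices and the generator's scope.

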