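# metabnet

Graph-theoretic analysis of brain glucose-metabolism covariance networks.

## What problem this solves, and for whom

Resting-state FDG-PET yields one number per brain region per subject: the
regional cerebral metabolic rate for glucose (CMRgl). Regions whose uptake
fluctuates together across subjects are taken to be functionally
associated, so a subjects x regions uptake table induces a *metabolic
covariance network*: nodes are the 90 regions of the AAL parcellation and
the edge weight between regions *i* and *j* is the interregional Pearson
correlation C_ij computed across subjects. metabnet is for researchers who
want to build these networks from regional uptake tables for several
diagnostic groups (e.g. normal controls, MCI, AD), characterize their
topology, and test where and how the groups differ — without access to
image-level processing, which is out of scope.

## The model

Per group, after brainstem-reference normalization and per-region OLS
removal of age, sex, age x sex, total CMRgl and regional volume, the
pipeline computes:

- **Connectivity**: C = (C_ij), symmetric 90 x 90, zero diagonal; resampled
  by N_boot = 300 subject bootstraps of 80% per group.
- **Binary graphs**: at sparsity degree s, keep the
  K = floor((1 - s) * 4005) pairs of largest |C_ij|, for s = 0.5, 0.52, ...,
  0.9 (21 values).
- **Attributes**: clustering index C (mean of C_i = 2e_i / k_i(k_i - 1)),
  characteristic path length L (mean geodesic distance), global efficiency
  E_glob (mean 1/d_ij), local efficiency E_loc (mean efficiency of
  neighbor-induced subgraphs), and small-worldness
  sigma = (C/C_rand) / (L/L_rand) against Maslov-Sneppen degree-preserving
  rewired nulls.
- **Nodal centrality**: betweenness B_i (Freeman/Brandes), normalized as
  b_i = B_i / \<B\>; hubs satisfy b_i > 1.5.
- **Group statistics**: edge-wise Fisher r-to-z with
  Z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3)) under Benjamini-Hochberg FDR
  (q = 0.05); Kruskal-Wallis on per-bootstrap areas under the attribute
  curves with Bonferroni post hocs; per-region Kruskal-Wallis NBC profiling
  with a >= 99%-of-grid significance rule; top-1000-edge lobe counts and
  mean-|r| covariation analyses for the lobes and the ten-region
  pericentral "Core" set.

A synthetic-cohort generator (`cohort_spec()`, `generate_cohort()`)
emulates the covariance structure this analysis assumes — strong homologous
L/R correlations, lobe blocks, group-specific hypometabolism and
covariance alterations, linear covariate effects — and is the test bed for
every stage. See `vignettes/metabnet-methods.Rmd` for assumptions, tunable
parameters, and design decisions.

## Worked example

```r
library(metabnet)

atlas  <- load_atlas()                       # builtin 90-region AAL table
spec   <- cohort_spec(seed = 42)             # 68 NC / 62 MCI / 69 AD
cohort <- normalize_reference(generate_cohort(spec, atlas))

# regional group differences (Bonferroni over 90 regions)
tt <- regional_group_ttests(cohort)
length(hypometabolic_regions(tt, "NC-AD"))   # 23
length(hypometabolic_regions(tt, "NC-MCI"))  # 10

# the NC metabolic network
res <- remove_confounds(subset_group(cohort, "NC"))
C   <- pearson_matrix(res)
C["PreCG.L", "PreCG.R"]                      # 0.623  (homologous pair)

g <- binarize(C, 0.9)                        # keep top 10% of |r|
g$k_edges                                    # 400
g$threshold                                  # 0.287  (realized R_k)

set.seed(1)
sw <- small_world_sigma(g, n_null = 50)
sw$sigma                                     # 3.08 (gamma 3.42, lambda 1.11)
```

The 23 and 10 hypometabolic regions are exactly the sets the generator
planted (20% and 10% uptake reductions); the homologous correlation
recovers the planted 0.7 attenuated by noise and confound regression; and
sigma > 1 with lambda near 1 says the thresholded network is small-world:
clustered like a lattice, integrated like a random graph.

## The analysis workflow

The numbered scripts under `analysis/` run the full study on a synthetic
cohort at the reference group sizes and narrate what they find; each writes
its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # cohort with planted effects
Rscript analysis/02_regional_differences.R # hypometabolism t-tests
Rscript analysis/03_connectivity.R         # matrices + Fisher/Z comparisons
Rscript analysis/04_network_attributes.R   # attribute curves, AUC KW, sigma
Rscript analysis/05_nbc_hubs.R             # NBC profile, hub tables
Rscript analysis/06_lobes_core.R           # lobe counts, Core covariation
```

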