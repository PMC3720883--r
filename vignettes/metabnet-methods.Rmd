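---
title: "Glucose-metabolism covariance networks: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glucose-metabolism covariance networks: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Regional cerebral glucose metabolism (CMRgl), measured by resting-state
FDG-PET, declines in characteristic regional patterns in Alzheimer's disease
(AD) and mild cognitive impairment (MCI). Beyond region-by-region
hypometabolism, regions whose uptake rises and falls *together across
subjects* are taken to be functionally associated: the subjects-by-regions
uptake matrix induces a 90-node *metabolic covariance network* whose edges
are interregional Pearson correlations. metabnet implements the full chain
from a regional uptake table to group comparisons of that network's
topology — segregation (clustering index, local efficiency), integration
(characteristic path length, global efficiency), small-world balance
(sigma), and nodal influence (normalized betweenness centrality, NBC).

The pipeline is cross-sectional: correlations are computed **across
subjects**, so a single network exists per group, not per subject. All group
inference therefore rests on subject bootstraps of the correlation matrix.

## Pipeline stages and their assumptions

1. **Reference normalization.** Each subject's regional uptake is divided by
   that subject's brainstem mean uptake. The brainstem is relatively
   preserved in the AD spectrum; normalizing by the cerebral global mean
   would itself be depressed in patients and bias hypometabolism estimates
   toward zero. Assumption: the reference region is disease-neutral.
2. **Confound regression.** Per region, ordinary least squares removes age,
   sex, age x sex, total uptake (the sum over the 90 regions), and the
   region's structure volume (a partial-volume proxy). Education is screened
   first: it enters the final design only if some region shows a significant
   marginal effect at the family level (see *Numerical choices*). Residuals
   replace the raw values. Assumption: confound effects are linear and
   additive.
3. **Connectivity.** Pearson correlation across subjects per region pair;
   diagonal zero. Partial correlations are deliberately not offered: with 90
   regions and fewer subjects per group the inverse covariance is not
   estimable without regularization, which would change the estimand.
4. **Bootstraps.** 300 subject subsets of 80% per group (defaults), each
   giving one correlation matrix. Subsets are drawn *without* replacement
   within a sample and independently across samples; a flag enables
   with-replacement draws. This choice reads "resampling with replacement
   from sample to sample" as between-sample independence — the 80% subset
   size makes within-sample replacement the less natural reading, and
   without-replacement subsets keep the degenerate `fraction = 1` case equal
   to the full sample exactly.
5. **Binarization.** At sparsity degree `s`, keep the
   `K = floor((1 - s) * 4005)` pairs of largest absolute correlation; the
   grid runs 0.5 to 0.9 in steps of 0.02 (21 values). Using `floor`
   guarantees the realized sparsity is at least nominal and makes
   `s = 0.9 -> K = 400` exact. Ties at the threshold (measure-zero for
   continuous data) are broken by atlas-order pair index so runs are
   reproducible. Absolute value is used throughout; signed variants of the
   ranking exist only in `top_k_edges(signed = TRUE)`.
6. **Graph attributes.** Computed on the binary graphs with these
   conventions, each verified against brute-force oracles in the test suite:
   clustering of nodes with degree < 2 is 0; path length on fragmented
   graphs averages over connected pairs only (a strict mode errors instead);
   efficiency assigns disconnected pairs 1/inf = 0; betweenness uses
   fractional credit across equally short paths; NBC is `b_i = B_i / <B>`
   and is flagged undefined (not silently zeroed) when every `B_i` is zero.
7. **Null models and sigma.** Degree-preserving Maslov-Sneppen rewiring with
   10 attempted double-edge swaps per edge per draw; sigma uses 100 null
   draws by default (both exposed as parameters — the reference methodology
   does not fix them). Sigma is computed on the largest component when the
   graph is fragmented.
8. **Group statistics.** Edge-wise Fisher r-to-z with
   `Z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` on the *full-sample* group
   matrices (the formula's `N1`, `N2` are group sizes, which pins this
   choice over bootstrap-aggregated matrices), Benjamini-Hochberg FDR at
   `q = 0.05` over the 4005 pairs. Global attributes are summarized per
   bootstrap by the trapezoidal area under the 21-point curve and contrasted
   by Kruskal-Wallis with pairwise rank-sum post hocs, Bonferroni x3 —
   Bonferroni is the conservative, reproducible reading of an unspecified
   "multiple comparisons" procedure. Because bootstrap AUCs from one group
   share subjects, these p-values describe bootstrap separation between
   group networks, not subject-level inference; they are reported as such.
9. **NBC differences and hubs.** NBC is profiled per region, bootstrap and
   sparsity degree, restricted to the contiguous low-sparsity range where
   every bootstrap graph of every group is fully connected (so all NBC
   values come from connected networks). Kruskal-Wallis per region and grid
   point, Bonferroni over the 90 regions — not 90 x 21, because the
   "significant at >= 99% of grid points" rule already integrates over the
   grid. Hubs are regions with mean NBC (over bootstraps and grid) above
   1.5.
10. **Lobe and Core analyses.** The 1000 largest-|r| edges are counted per
    lobe; within- and between-set mean |r| is computed for the five named
    lobes and for the ten-region pericentral "Core" set (bilateral
    precentral, supplementary motor, median cingulate, postcentral,
    paracentral), with Core members removed from the frontal and limbic
    target sets before the Core-lobe contrasts. Regions outside the five
    named lobes (central region, subcortical nuclei) contribute only to
    cross-lobe counts.

## The synthetic cohort generator

Restricted clinical data cannot ship with the package, so
`generate_cohort()` produces cohorts carrying the second-order structure the
analysis assumes:

- **Homologous pairs.** Left/right counterparts correlate at 0.7 by default —
  the dominant empirical feature of interregional uptake correlation
  matrices.
- **Lobe blocks.** Within-lobe correlation 0.4, background 0.1.
- **Group differences.** Defaults emulate the qualitative AD-spectrum
  pattern: in AD, frontal (0.55) and occipital (0.60) within-lobe
  correlations rise while temporal/limbic (0.25) and the Core block (0.30
  versus 0.60 in controls) weaken; MCI sits between. Group mean reductions
  (hypometabolism) default to 20% in a 23-region temporo-parietal /
  limbic / occipital set for AD and 10% in a 10-region limbic/temporal set
  for MCI, matching the topography and set sizes such studies report. The
  source studies print no correlation-difference or uptake effect sizes, so
  the magnitudes are this package's own calibration, chosen once for
  recoverability at realistic group sizes (about 60-70 subjects per group)
  and documented here; they are not fitted to any reported statistic.
- **Covariates.** Age ~ U(55, 90), sex ~ Bernoulli(1/2), education
  ~ U(8, 20), volumes lognormal, with small linear effects on uptake
  (defaults: -0.002/year age, 0.02 sex, 0.001 age x sex interaction,
  2e-6/mm^3 volume, 0 education so the screen behaves as a null test); a
  per-subject reference uptake multiplies the profile so the emitted table
  is on the raw tracer scale and normalization must actually undo it.
- **Construction.** The target correlation matrix is assembled blockwise
  (background, lobe, Core, homologous, explicit edge overrides, in rising
  precedence) and is then *repaired*: block matrices of this kind are
  usually mildly indefinite, so negative eigenvalues are clipped at zero and
  the diagonal rescaled to one. The repair is recorded in the returned
  attributes; construction aborts if the matrix is far from positive
  semi-definite. Groups are drawn from multivariate normals with independent
  RNG streams derived from `(seed, group)`, so adding a group never perturbs
  another group's draw.

What the generator does **not** emulate: PET acquisition physics,
partial-volume effects beyond a linear volume covariate, non-Gaussian or
heavy-tailed uptake distributions, spatial autocorrelation beyond the block
structure, site/scanner effects, and longitudinal drift. Passing tests on
synthetic cohorts therefore validate the *statistical machinery* — that
planted effects of known location and size are recovered at the documented
rates — not any clinical claim about real populations.

## Numerical choices

- **Education screen.** The drop rule is family-level: per-region marginal
  p-values are Bonferroni-adjusted over the 90 regions and the covariate is
  kept only if some adjusted p <= alpha. An unadjusted per-region rule
  would retain a null covariate in most cohorts purely by multiplicity;
  the family-level rule drops a null covariate in about `1 - alpha` of
  cohorts, which is the behavior a screen is meant to have.
  `adjust = "none"` restores the literal per-region rule.
- **Group contrasts.** The "t test" on regional uptake is the contrast
  t-statistic from the full linear model with group entered as a factor
  beside the confounds (pooled variance, residual degrees of freedom) —
  equivalent to a classical two-sample t on confound-adjusted means, and
  the natural reading when group sits inside the regression.
- **Total uptake** is computed after reference normalization (the stages
  run in that order); it is used in the connectivity confound model but not
  in the group-contrast model, where it would absorb the group effect
  under study.
- **PSD repair tolerance.** Construction errors when the minimum eigenvalue
  is below `-0.5 * N`; below that the requested structure is
  self-contradictory rather than numerically indefinite.
- **Degenerate inputs.** Correlation needs >= 4 subjects; constant residual
  columns, non-positive references, rank-deficient designs, empty graphs,
  and all-tied samples raise informative errors rather than propagating
  NaN.

## Problem sizes used in validation

The shipped tests and the acceptance script run the full machinery at sizes
chosen to exercise every code path while completing comfortably on a single
CPU: graph-metric oracle equivalence exhaustively over all 1,105 labeled
graphs on up to 5 nodes plus 200 random graphs up to 25 nodes; 1,000
rewiring draws for degree conservation; 500 replicates for the FDR and
Kruskal-Wallis calibration (30 regions, 150 subjects per group); 10 seeds
each for the three planted-effect recovery studies; and the end-to-end
synthetic study at the reference group sizes (68 NC / 62 MCI / 69 AD) with
50 bootstraps. The `analysis/` scripts use the same settings and write
their tables under `results/`.

## Known limitations

- Edge-wise Fisher/Z comparisons at 60-70 subjects per group have little
  power for correlation differences of realistic size once FDR-corrected
  over 4005 pairs; the bootstrap-based AUC, Core, and lobe analyses are the
  sensitive instruments at these sample sizes, and the synthetic defaults
  reflect that.
- The NBC connectivity restriction can shrink the usable sparsity range to
  the dense end of the grid when bootstrap networks fragment early.
- Bootstrap-derived p-values understate subject-level uncertainty (shared
  subjects across bootstraps); they order groups reliably but their
  magnitudes should not be read as population inference.
- Binarization by rank makes all downstream topology invariant to monotone
  transformations of |r|, which is a feature for comparability and a
  limitation for effect-size interpretation.
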