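---
title: "Methods: developmental analysis of structural brain connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developmental analysis of structural brain connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectodev)
```

## The analysis in outline

`connectodev` implements a connectomic analysis of brain-network development
in case-control cohorts. The motivating setting is intrauterine growth
restriction (IUGR) in preterm-born children: three cross-sectional cohorts
(ages 1, 6 and 10 years), each split into controls and IUGR cases, with
diffusion-MRI connectomes and age-appropriate neurobehavioral scores per
subject. The pipeline covers five stages:

1. **Node definition.** Network nodes are anatomical parcels. Starting from
   a 90-region cortical/subcortical inventory plus 16 cerebellar parcels,
   the cerebellar parcels are merged by laterality into left cerebellum,
   right cerebellum and vermis, giving 93 nodes.
2. **Connectome construction.** Two regions are connected when at least one
   tractography streamline has endpoints assigned to both (self-loops
   excluded). Three variants are built per subject: *binary* (presence),
   *FA-weighted* (mean fractional anisotropy of the streamlines linking the
   pair) and *FA-normalized* (FA weights divided by the total FA weight of
   all connections, so total network strength is exactly 1).
3. **Graph metrics.** Per variant: average degree, average strength, global
   efficiency (integration), local efficiency and average clustering
   coefficient (segregation) — 11 values per subject.
4. **Group statistics.** Covariate-adjusted case-control comparison by
   ordinary least squares (gender and maternal education as cofactors,
   gestational age as covariate, plus age at scan for metrics or age at
   test for scores), and partial correlations between age-residualized
   metrics and scores with gender, gestational age, maternal education and
   group as confounders.
5. **Developmental trajectories.** Second-order polynomial fits of each
   metric against age, per group, fit descriptively.

## Definitions and numerical conventions

**Endpoint assignment.** A streamline endpoint takes the label of its
containing voxel. Endpoints in unlabeled (background) voxels are assigned
the nearest labeled voxel within a Euclidean radius of 2 voxels, with ties
broken toward the lowest label. Rationale: deterministic tractography stops
near the white-matter/gray-matter interface (FA stop threshold 0.1), so an
endpoint can sit just outside the labeled gray matter. Endpoints that remain
unassignable, endpoints outside the grid, and same-region pairs are
discarded and counted by reason.

**FA aggregation.** The weight of a connection is the unweighted arithmetic
mean of the per-streamline mean-FA values linking the pair — streamline
length does not enter.

**Normalization.** "Total FA weight of all the connections" counts each
undirected edge once; the normalized connectome therefore satisfies
`sum(W[upper.tri(W)]) == 1` to machine precision, and normalization is
invariant to uniform rescaling of the input weights. Which counting
convention (once vs. twice) the original analyses used is not recoverable
from their reported magnitudes; the once-counted rule is the stated
construction and is what this package implements, without attempting to
match any published normalized-metric magnitude.

**Path lengths.** Binary distance is the hop count. Weighted distance maps
each step to length `1/weight` — stronger (higher-FA) connections are
shorter — and minimizes the summed length (Floyd–Warshall over the dense
length matrix, implemented in C++). Disconnected pairs contribute 0 to
efficiency. Global efficiency is the mean of `1/d(i,j)` over ordered pairs.

**Local efficiency.** Mean over nodes of the global efficiency of the
subgraph induced by each node's neighbors (the node itself excluded),
retaining the original weights within the subgraph; nodes with fewer than
two neighbors contribute 0.

**Clustering.** Binary clustering is the triangle fraction
`2 t_i / (k_i (k_i - 1))`. Weighted clustering uses the Onnela
geometric-mean triangle intensity on weights rescaled by the network-wide
maximum; with 0/1 weights this reduces exactly to the binary formula. The
choice follows the standard reference conventions for these measures; the
maximum-rescaled form makes the statistic scale-free, which is why the
FA-weighted and FA-normalized variants of a subject share one clustering
value.

**Group averages.** The average connectome of a group is the entrywise mean
with absent edges contributing 0 (the convention is not otherwise
determined by the construction). High-FA display edges are those with
weight strictly greater than the threshold (default `tau = 0.3`).

**Statistics.** The group comparison reports the group-indicator
coefficient of the OLS fit with a two-sided t-test; with no covariates this
is exactly the pooled two-sample t-test. The partial correlation is the
Pearson correlation of the residuals of both variables on the confounders,
with `df = n - 2 - k` for `k` confounders (the df convention is not fixed by
the source analyses; both `df` and `n` are reported). Gender is coded 0/1
and maternal education as one ordinal numeric column (three levels); no
multiple-comparison correction is applied, mirroring the original analysis
design — raw p-values are always retained so users can correct post hoc.
Missing covariates cause listwise deletion with a logged count.

**Trajectories.** Quadratic fits default to subject-level points; an
`on_means = TRUE` mode collapses each (group, age) cell to its mean first,
in which case three distinct ages are interpolated exactly. Ages enter in
years as recorded, not as cohort indices.

## The synthetic cohort generator

No imaging or score data are distributed with the analysis this package
implements, so the generator is a first-class module that emulates the
study's *statistical structure*, and every downstream stage is exercised
against it.

The generative model is deliberately the simplest one whose induced metrics
are tunable:

* **Edges** are Bernoulli draws with a per-subject connection density.
  Expected mean degree is linear in density, so the density solving a
  target degree has the closed form `p = degree / (n - 1)`; the
  between-subject spread of the latent density is solved so that the
  observed degree SD (Bernoulli sampling noise plus latent spread) matches
  its target.
* **Weights** are truncated normal on [0, 1]; the location parameter is
  solved by root-finding so the *truncated* mean hits the target FA weight
  (this is where genuine iteration is needed — the truncated mean is not
  linear in the location).
* **Covariates** (gestational age, ages at scan and test, gender, a
  three-level ordinal maternal-education factor) are drawn independently
  from the per-cell design distributions.
* **Scores** are built as a linear function of the linked metric's
  confounder-adjusted residual plus an age-at-test trend and Gaussian noise
  whose variance is solved from the target partial correlation
  (`sd_noise = sd_resid * sqrt(1 - rho^2) / |rho|`), then affinely rescaled
  to the instrument's mean and SD (developmental quotients: 100 ± 15).
  Affine maps in the regressors are removed exactly by the residualization
  steps, so the calibration is analytically exact in population terms.

Default design cells encode the published cohort conditions: group sizes
7/8, 8/10 and 8/8 at ages 1, 6 and 10; gestational ages near 31–33 weeks;
and per-cell degree and FA-weight targets taken from the published group
means and SDs. The published strength statistic changes units across ages
(average nodal strength at 1 year, average edge weight at 6/10 years); the
defaults convert accordingly (edge weight = nodal strength / degree at
1 year). Gender proportion (0.5) and education proportions (0.3/0.4/0.3)
are not reported anywhere and are fixed once at values typical for such
cohorts.

**What the generator controls and what it does not.** Degree and strength
are controlled directly and are calibrated to within half a generated SD at
n ≥ 50 per cell. Efficiencies and clustering are *emergent*: they follow
from density and weights, which preserves the qualitative group ordering —
lower degree and weights in the IUGR cells produce lower binary and
FA-weighted efficiencies and, through the unit-strength normalization,
*higher* FA-normalized efficiencies — but their absolute levels are
whatever an independent-edge model yields. No simple edge-independent model
can pin all eleven metric means simultaneously, and the generator does not
try. Consequently, passing tests demonstrate the pipeline's correctness and
the directional group structure, not that the generator reproduces real
cortical topology (no spatial embedding, no modules or hubs, no
within-subject covariance beyond what density and weight levels induce, and
cross-sectional cells only — no longitudinal correlation).

```{r cohort, eval = FALSE}
design <- default_cohort_design(ages = 1, n_per_group = 50, seed = 1)
cohort <- simulate_cohort(design)
metrics <- cohort_metric_table(cohort)
scores <- simulate_scores(cohort, metrics)
battery <- run_case_control_battery(cohort_metadata(cohort), metrics, scores)
```

## Parameters that matter

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `radius` | `endpoints_to_regions()` | 2 voxels | background search radius at the WM-GM interface |
| `fa_floor` | `make_toy_streamlines()` | 0.1 | tractography FA stop threshold, applied as a floor on generated per-streamline FA |
| `tau` | `threshold_edges()` | 0.3 | strict threshold for high-FA display edges |
| `alpha`, `trend_alpha` | `run_case_control_battery()` | 0.05, 0.1 | significance and trend flags (raw p-values always kept) |
| `weight_sd_within` | `cohort_design()` | 0.05 | within-subject spread of edge FA values |
| `n_nodes` | `cohort_design()` | 93 | connectome size (merged parcellation) |

## Degenerate inputs and tie-breaks

* An all-zero connectome cannot be normalized (error), but an edgeless
  normalized *container* is representable so an empty subject still has a
  metric row (all metrics 0).
* Nodes with fewer than two neighbors contribute 0 to clustering and local
  efficiency; disconnected pairs contribute 0 to efficiency.
* Nearest-label ties at equal distance resolve to the lowest label;
  Voronoi ties in the toy parcellation resolve to the first (lowest) seed.
* Constant ages make age-residualization an error, constant gender (e.g.
  an all-male cohort) makes the design matrix rank-deficient — reported
  with the offending column's name.
* Matrix files asymmetric beyond 1e-9 are rejected; smaller asymmetries are
  symmetrized exactly on read.

## Problem sizes used in the shipped checks

The package's own verification uses sizes chosen to make each claim
decisive at desk scale: metric oracles on 50 random graphs of 5–20 nodes
against exhaustive Floyd–Warshall / triangle-enumeration references
(tolerance 1e-9, with igraph as an additional independent
cross-implementation); type-I error of the adjusted comparison over 1,000
null replicates at n = 60; partial-correlation recovery at n = 500;
calibration and directional-pattern checks on 93-node cohorts with 50
subjects per group, the directional pattern over 100 seeded runs. The
acceptance script regenerates its quantities from scratch at run time from
a supplied seed.

## Known limitations

* The generator's graphs are edge-independent: realistic clustering levels,
  community structure and spatial constraints of cortical networks are out
  of scope, as is any claim about absolute efficiency/clustering levels.
* Weighted local efficiency retains original weights in neighbor subgraphs
  (no per-subgraph re-normalization); other conventions exist.
* Whether the source analyses adjusted partial-correlation degrees of
  freedom for the confounder count is unknown; this package subtracts it
  and reports both `df` and `n`.
* Raw-imaging ingestion (NIfTI label volumes, TRK/TCK streamlines) is out
  of scope; delimited text is the canonical interchange, with GraphML
  export for visualization.
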