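---
title: "Weighted cortical network efficiency: models, parameters and design choices"
author: "cortnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted cortical network efficiency: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortnet)
```

# The analysis in one paragraph

`cortnet` analyses group and task-condition differences in the efficiency
of cortical functional networks. For each subject and listening condition,
a regions x blocks response matrix is reduced to a matrix of zero-lag
Pearson correlations between all region pairs. Thresholding the absolute
correlations at a fixed *cost* (the fraction of retained edges out of all
`N(N-1)/2` possible pairs) yields a weighted graph whose edge weights are
the absolute correlations, comparable across subjects because every
network has the same number of nodes and edges. On these graphs the
package computes Latora–Marchiori global efficiency
`E_glob(i) = (1/(N-1)) * sum_j 1/L_ij` and local efficiency (the same
quantity inside the subgraph induced by a node's direct neighbours), with
shortest path lengths `L_ij` accumulated over reciprocal weights `1/w`
(stronger correlations are functionally closer). Both measures are
normalized by the mean values of 50 degree-preserving Maslov–Sneppen
surrogate networks and averaged over a cost grid from 0.10 to 0.40 in
steps of 0.02. The resulting per-subject, per-condition summaries enter a
2x2 repeated-measures mixed ANOVA (group between subjects, condition
within), a per-region exploratory screen at uncorrected p < 0.05,
Shapiro–Wilk-gated Pearson correlations with mean cortical thickness, and
pooled-variance t-tests on head motion.

# Conventions and numerical choices

* **Fixed cost by rank selection.** A network at cost `c` keeps exactly
  `round_half_up(c * N(N-1)/2)` edges with the largest `|r|`; the realized
  cutoff `r_c` is the smallest retained `|r|`. Rank selection makes the
  edge count exact (and the edge sets nested across costs), which is what
  enables cross-subject comparison; with continuous data ties are
  measure-zero, but a deterministic tie-break on ascending node indices is
  used anyway. Negative correlations contribute their absolute value and
  their sign is discarded.
* **Shortest paths.** Edge length is `1/w`. Dijkstra/Floyd–Warshall
  implementations in C++ are interchangeable here; both are validated
  against exhaustive simple-path enumeration on small graphs to 1e-12.
  Unreachable pairs contribute zero efficiency (1/Inf = 0) rather than
  being dropped, keeping denominators fixed across networks.
* **Local efficiency stays inside the neighbourhood.** Paths between the
  neighbours of node `i` are computed strictly within the neighbour-induced
  subgraph. The literature variant that routes neighbour-to-neighbour paths
  through the whole graph is deliberately not used. Nodes with degree < 2
  have `E_loc = 0` and remain in the network average, so averages are over
  a fixed node set at every cost.
* **Surrogates.** Double-edge swaps `(a,b),(c,d) -> (a,d),(c,b)` are
  attempted `10 x |E|` times, rejecting self-loops and duplicates; each
  surviving edge carries its weight with it, so the degree sequence and
  the weight multiset are conserved exactly. Strength sequences (weighted
  degrees) are not conserved; strength-preserving nulls are a different
  estimand and out of scope. Nodal values are normalized by the surrogate
  *network average* efficiencies, not by per-node surrogate values.
  Graphs that admit no valid swap (e.g. a triangle) are returned
  unchanged with a message.
* **Mixed ANOVA from sums of squares.** With a two-level within factor,
  sphericity holds trivially and the sums-of-squares decomposition gives
  the exact `F(1, n-2)` tests: the group effect against
  subject-within-group error, condition and interaction against the
  condition x subject error. The implementation is cross-checked in the
  test suite against `aov()` with an `Error(subject/condition)` stratum to
  1e-10. Unbalanced groups are computed with weighted cell means and
  flagged with a warning.
* **Degenerate inputs.** Zero-variance regions are an error naming the
  region; constant accuracy regressors fall back to demeaning with a
  warning; zero surrogate mean efficiency (possible for very sparse
  graphs) is an error rather than an Inf.

# The synthetic cohort generator

No response data are distributed with the package; the generator exists so
that every downstream stage can be tested against a known ground truth. It
emulates the *statistical structure* of a two-group listening study: 12
younger and 12 older adults, quiet and noisy conditions, 66 cortical
regions (33 per hemisphere), 60 task blocks per condition.

Each subject/condition response matrix is drawn as 60 independent samples
from a zero-mean multivariate normal whose covariance is a structured
coupling matrix plus `noiseSd^2` observation noise on the diagonal.
Because the pipeline consumes only zero-lag correlations, independent
block samples are sufficient: no hemodynamics, temporal autocorrelation or
block-ordering structure is modelled, and the generator treats blocks as
exchangeable.

The coupling template has:

* `nModules = 6` contiguous modules with intra-module coupling
  `wIn = 0.55` and inter-module baseline `wOut = 0.25`;
* a seeded random 15% of inter-module pairs promoted to long-range "hub"
  shortcuts at `wHub = 0.55` — the shortcuts that give the planted
  networks their small-world character (high local efficiency from the
  modules, moderate global efficiency from the shortcuts);
* positive semidefiniteness enforced by eigenvalue clipping at 1e-8
  followed by rescaling to unit diagonal (a cheap Cholesky certificate is
  tried first and the repair only runs when it fails).

The inter-module baseline is deliberately not tiny: with near-zero
background coupling the retained edge weights become strongly bimodal
(strong intra, weak inter), and at dense costs a degree-preserving
randomization of such weights *beats* the modular original on weighted
local efficiency, destroying the small-world signature the generator is
supposed to plant. `wOut = 0.25` keeps normalized local efficiency above 1
and normalized global efficiency below 1 for every subject, condition and
grid cost.

Planted effects, all expressed as modifications of this template:

* **Group deficit (`deltaGroup = 0.30`).** All long-range couplings
  (baseline and hubs) are multiplied by `1 - deltaGroup` in the older
  group, thinning their retained shortcuts at fixed cost and lowering
  normalized global efficiency. Calibrated by simulation so that the
  group main effect on cost-averaged normalized `E_glob` is detected at
  p < .05 in essentially every 12-vs-12 cohort (observed power 1.00 over
  25 replicates at a reduced cost grid).
* **Interaction (`deltaInteraction = 0.40`).** Intra-module coupling of
  the *task-modulated* modules — the first half of the modules, mirroring
  the regional specificity of real condition effects — is multiplied by
  `1 +/- deltaInteraction/2` in the noisy vs quiet condition, with
  opposite sign in the two groups (younger up in noise, older down).
  At fixed cost this shifts the balance between modulated intra-module
  edges and hub edges near the retention cutoff, moving normalized local
  efficiency with a group x condition interaction (observed power 1.00).
  Modulating *all* modules instead would mostly rescale weights that the
  surrogate normalization cancels; restricting the modulation to a module
  subset is what makes the effect topological. Because modularity couples
  the two measures, the same mechanism also leaves traces on normalized
  global efficiency (an opposite-signed interaction and condition
  effects) — side effects a single coupling-based generator cannot fully
  avoid, so the planted pattern is a superset of, not a replica of, the
  sparse effect table such studies typically report.
* **Thickness link.** Each subject carries a latent long-range coupling
  factor `f ~ N(1, subjectSd = 0.08)`; the group attenuation multiplies
  it. Thickness is `2.5 mm + 0.7 * (factor - 1) + N(0, 0.08 mm)`, giving
  a realistic ~0.2 mm group difference and a positive association between
  thickness and normalized global efficiency. One caveat discovered
  during calibration: within single conditions the planted interaction
  can distort or even invert the thickness ordering, so the covariate
  analysis reports per-condition rows *and* a condition-averaged row, and
  the generator's thickness property is stated for the condition-averaged
  summary.
* **Accuracy.** Per-block accuracy is `Binomial(4, p)/4` (four trials per
  block), with means 0.97/0.85 (younger quiet/noisy) and 0.95/0.60 (older),
  reproducing a large group gap only in noise. By default accuracy does
  not feed back into the responses; setting `accuracyConfound > 0` adds a
  uniform accuracy-locked signal to every region, planting a network
  difference that is carried entirely by accuracy and is removed exactly
  by the residualization step (the signal is linear in the regressor).
* **Motion.** Log-normal per-subject summaries (median ~0.12 mm),
  identically distributed in both groups — the motion control analysis
  should find nothing.

With `deltaGroup = 0` and `deltaInteraction = 0` the groups are
exchangeable by construction: group labels enter the generative model only
through those two parameters (and through accuracy means, which do not
affect responses unless the confound is enabled).

What passing tests on this generator do *not* show: robustness to
hemodynamic confounds, autocorrelated noise, registration or parcellation
error, or non-Gaussian response distributions. The generator validates the
pipeline's statistical logic, not the physics of fMRI.

# Residualization of task accuracy

`networkMetrics(..., residualize = TRUE)` regresses each region's response
row on an intercept and per-block accuracy by OLS and correlates the
residuals instead. The regression is fit per subject on the *concatenated*
blocks of both conditions and the residuals are re-split by condition,
matching the convention of removing performance effects from the
functional data globally before re-running the whole analysis. Fitting per
condition instead would also remove condition-mean differences, which are
part of the signal of interest.

# Problem sizes used by the test suite

Simulation studies in the acceptance tests run at sizes chosen to keep the
suite practical on one CPU while preserving the study's sampling
structure: the type-I calibration uses 400 null cohorts at three low grid
costs with 10 surrogates per network; the power and covariate studies
share one set of 100 default cohorts at two grid costs; the small-world
check uses 50 surrogates (the analysis default) at three costs spanning
the grid. The acceptance script runs the full 16-level grid with 50
surrogates once. Cost-averaging over a subset of the grid is an unweighted
mean over the levels used, exactly as for the full grid.

# Known limitations

* The mixed ANOVA is exact only for two-level factors; more conditions
  would need sphericity handling (not implemented, not needed here).
* Surrogate normalization uses the ensemble mean only; no empirical null
  p-values are derived from the surrogate distribution.
* The regional screen is intentionally uncorrected (an exploratory
  convention); `regionalEffects(bhCorrect = TRUE)` applies
  Benjamini–Hochberg within measure x effect families as an extension,
  off by default.
* The Spearman fallback in `covariateAssociation()` extends the original
  normality-gated procedure (which reported all variables normal); the
  flag `normalityPass` records which branch was taken.
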