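---
title: "Modelling longitudinal cortical trajectories vertex-wise with surflmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal cortical trajectories vertex-wise with surflmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surflmm)
```

## The model

surflmm analyses longitudinal surface-based morphometry: cortical thickness
(CT, mm) or surface area (SA, mm²) sampled at the vertices of a triangulated
cortical mesh, with subjects scanned between one and six times at irregular
intervals across development. At every vertex the measure for subject $i$ at
scan $j$ is modelled as a polynomial in age with group-specific shape and a
subject-level random intercept and slope:

$$
y_{ij} = \beta_0 + \beta_{g} g_i + \beta_{a1} a_{ij} + \beta_{ag1} g_i a_{ij}
       + \beta_{a2} a_{ij}^2 + \beta_{ag2} g_i a_{ij}^2
       + \mathbf{x}_{ij}^\top \boldsymbol\gamma
       + u_{i0} + u_{i1} a_{ij} + \varepsilon_{ij},
$$

where $g_i$ codes group membership against a declared reference level
(dummy coding; any number of groups $k \ge 2$ is supported with $k-1$
dummies per term), $\mathbf{x}_{ij}$ holds nuisance covariates (sex and
scanner as unordered factors; standardized intracranial volume for SA
analyses only), $(u_{i0}, u_{i1})$ is a zero-mean bivariate normal subject
effect with unstructured covariance $G$, and
$\varepsilon_{ij} \sim N(0, \sigma^2)$. Three nested orders are considered:
constant (no age terms), linear, and quadratic. Unbalanced designs —
subjects with a single scan, irregular visit spacing — are handled naturally
by the marginal likelihood.

Why mixed models: longitudinal cohorts of this kind have highly variable
scans-per-subject counts and inter-scan intervals, so ordinary regression
on scans would both understate uncertainty (repeated measures) and waste
the within-subject information that identifies individual slopes.

## Estimation

Models are fitted by full maximum likelihood (ML), not REML. This is a
deliberate choice: per-vertex model-order selection by BIC and
likelihood-ratio tests between models that differ in *fixed* effects are
only valid under ML. The likelihood is profiled: given the relative
Cholesky factor $\Lambda$ of the random-effect covariance
($G = \sigma^2 \Lambda\Lambda^\top$), the GLS fixed effects and $\sigma^2$
have closed forms, leaving a 1-parameter (constant order) or 3-parameter
(linear/quadratic) optimization. The profiled deviance and its analytic
gradient reduce to per-subject cross-products, so one evaluation costs
$O(\text{subjects} \times p^2)$ independent of the number of scans; this is
what makes whole-surface permutation loops tractable. Optimization uses
BFGS with backtracking from a fixed, data-independent start (relative
intercept scale 0.1, slope scale 0.1/sd(age)), escalating deterministically
to a second start and a Nelder-Mead polish when the gradient does not
vanish at the returned point. There is no random initialization anywhere,
so refitting identical inputs is bitwise reproducible — a property the
permutation machinery relies on and the tests assert.

Numerical choices worth knowing:

* Age is centered at the pooled mean age before fitting (configurable via
  `age_center`), for conditioning of the quadratic column. Predictions and
  rates are reported on the original age axis.
* Constant-order models carry a random intercept only: a random slope
  without any fixed age trend is not a meaningful model, and many subjects
  contribute a single scan.
* When the fitted random-slope variance is essentially zero (relative
  slope SD below `fallback_tol = 1e-4`) the vertex is refit with a random
  intercept only and flagged `fallback_applied`; parameter counts used by
  BIC then reflect the reduced structure.
* The residual variance is floored at `1e-10` mm² so noise-free data (used
  by the interpolation tests) remain well-defined; the GLS fixed effects
  are exact in that limit.
* Convergence tolerance is `1e-8` (relative, on the deviance), at most 500
  iterations per start.
* A closed-form marginal-likelihood oracle (`marginal_loglik`, dense
  per-subject multivariate normal algebra) is kept entirely separate from
  the optimizer and is used by the test suite to verify every fit path;
  `lme4` serves as a second, external cross-check on moderate fixtures.

## Model-order selection

`surf_lmm()` fits every allowed order (default `0:2`; use `0:1` in small
subgroup analyses to avoid overfitting) and selects per vertex the order
minimizing $\mathrm{BIC} = -2\ell + k\log n$, where $n$ counts *scans* at
the vertex. Observations rather than subjects in the penalty is the common
mixed-model convention; it is declared explicitly because either choice is
defensible. Ties within $10^{-9}$ go to the lower order (parsimony). The
full BIC table is retained in the fitted object for audit.

## Inference

Group and shape effects are tested vertex-wise with likelihood-ratio
tests against reduced models:

* `effect = "group"` removes *all* group terms (offset and interactions) —
  a model with no group differences at all; df per non-reference level is
  $1 + \text{order}$.
* `effect = "shape"` removes only the interaction terms — both groups keep
  the same curve shape; df per level is the order, and order-0 vertices
  return $p = 1$ (there is no shape to test).

Removing the full set of group terms for the "group" contrast is a design
choice: testing the offset alone while retaining interactions would test a
quantity that depends on the (arbitrary) age centering.

Multiple comparisons across the surface are handled by cluster-wise
Monte-Carlo permutation: vertices with $p$ below the cluster-forming
threshold (default 0.01 — this threshold is unavoidably influential and is
therefore an explicit argument, not a hidden constant) are grouped into
connected components under mesh adjacency; group labels are then permuted
across *subjects* (all scans of a subject move together, covariates stay
attached to their scans), the p map is recomputed, and the maximum cluster
statistic per permutation forms the null. Corrected p values use the
add-one estimator $(1 + \#\{\text{null} \ge s\})/(1 + n_\text{perm})$, so
an observed statistic can never receive exactly zero. Designs with fewer
distinct label assignments than requested permutations switch to exhaustive
enumeration with a warning.

Two deliberate approximations, both documented rather than hidden:

* The per-vertex order map (and each vertex's random-effect structure) is
  frozen at its observed value during permutations. Re-running BIC
  selection inside every permutation would multiply the cost several-fold
  while changing the null only marginally.
* Covariates are not re-randomized and no residualization
  (Freedman-Lane-style) is applied; plain subject-label permutation is
  exact under the null of full exchangeability and a good approximation
  when covariates are roughly balanced between groups.

### Behaviour at desk scale

On the small validation meshes used throughout this package (42-vertex
icospheres) the maximum-cluster statistic is heavily tied: with a 0.01
forming threshold the expected number of suprathreshold vertices per null
map is below one, so the null distribution concentrates on sizes 0 and 1
and the Monte-Carlo test becomes conservative — the realized family-wise
error rate sits below the nominal 5% (around 3% in the 200-cohort
validation run). This is the familiar discreteness conservatism of
permutation tests with tied statistics, not a defect of the correction: on
application-scale meshes (tens of thousands of vertices, clusters of
hundreds of vertices) ties are immaterial. The validation suite reports
the realized FWER honestly rather than inflating it.

## Trajectories and snapshots

`predict_trajectory()` and `annual_rate()` evaluate the fitted fixed-effect
curve and its analytic derivative
$\beta_{a1} + \beta_{ag1} g + 2(\beta_{a2} + \beta_{ag2} g)(a - c)$ for a
group at an age, with covariates at reference levels (first factor level,
mean ICV); `snapshot_series()` assembles per-age vertex maps of the group
difference and of the difference in annualized rates — the age-resolved
"when and where do the groups diverge" view. For polynomials the analytic
derivative and a finite difference of yearly predictions coincide, so the
analytic form is implemented and the finite-difference agreement is a test.
Predictions outside the observed age range error out by default
(`guard = 0`); extrapolation must be requested explicitly.

## The synthetic cohort generator

`simulate_dataset()` exists so that every pipeline stage can be validated
end-to-end with known ground truth. It emulates the structure of a
two-scanner-era longitudinal developmental cohort:

* two (or more) groups; 1-6 scans per subject, i.i.d. from configurable
  weights or an exact per-subject allocation; first visit uniform in the
  age range, subsequent visits 1-4 years apart (schedules that would
  overrun the range are compressed into it);
* a shared quadratic baseline curve, default
  $3.81 - 0.0682a + 0.001136a^2$ mm — thinning of about 0.05 mm/year at
  age 8 decelerating to zero by age 30, the magnitude reported across
  developmental morphometry studies, and deliberately a *clearly*
  quadratic maturation regime;
* planted effects as hop-balls around seed vertices (connected by
  construction), adding group offsets and/or interaction terms for one
  group: the default case-control preset plants a +0.2 mm offset cluster
  and, at the most distant vertex, a -0.025 mm/year accelerated-thinning
  interaction cluster;
* subject random intercept/slope (SD 0.25 mm and 0.01 mm/year, correlation
  -0.2, raw-age scale) shared across vertices — emulating global
  anatomical offsets; scan noise independent across vertices (SD 0.1 mm);
  scanner offsets (0, +0.05, -0.03 mm) and a +0.05 mm sex offset;
* simulated thickness clamped at 0.5 mm to stay physiological at extreme
  ages.

What it does **not** emulate: realistic cortical geometry, spatially
correlated measurement noise, scanner-specific variance, or
FreeSurfer-specific error structure. Passing the validation suite therefore
demonstrates statistical correctness of the machinery, not robustness to
every property of real data; in particular, spatial noise correlation on
real surfaces makes the cluster-forming threshold even more influential
than it is here.

`study_design_replica()` reproduces a published cohort's printed totals
exactly at scale 1 (324 subjects/636 scans case-control; 108/244 for the
symptom subgroups, with the printed female counts, per-group scan totals
and 158/300/178 scanner quotas). Because i.i.d. scans-per-subject draws
cannot hit printed totals exactly, the replica solves a truncated-geometric
scans-per-subject distribution for the printed mean and converts it to an
exact integer allocation (largest-remainder rounding plus minimal adjacent
moves). The replica's female proportions use the integer counts from the
cohort's figure legend; the text's "58.1% female" for controls is
inconsistent with those counts (86/176 = 48.9%) and the integers were
preferred. The visit-interval distribution is declared (uniform 1-4 years),
not extracted from any source.

## Problem sizes in the validation suite

The simulation studies shipped with the package run on icosphere meshes of
12-42 vertices with cohorts of 24-200 subjects, 99-permutation nulls, and
50-500 replicates per study: large enough for the Monte-Carlo bands they
assert, small enough to run routinely. The same machinery scales to
application-size meshes vertex-by-vertex (fitting is linear in vertices;
permutation cost is vertices x permutations x fit cost).

## A worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(preset_config("case-control-default", seed = 7))
fit <- surf_lmm(sim$dataset)                      # fit + BIC selection
summary(fit)
cl <- cluster_inference(fit, "shape", n_perm = 99, seed = 7)
as.data.frame(cl)                                 # corrected cluster table
ss <- snapshot_series(fit)                        # per-age difference maps
plot(fit, vertex = cl$clusters[[1]]$peak_vertex)  # peak-vertex trajectories
```

## Conventions and limitations

* Inside R, vertices and triangles are 1-based (native R indexing); all
  on-disk dialects this package defines (triangle_text meshes, TSV maps,
  exported cluster tables) are 0-based, matching the wider surface-analysis
  tool ecosystem. FreeSurfer binary formats are read and written as-is.
* The analysis mask defaults to all vertices; a medial-wall-style exclusion
  is supplied as a per-vertex mask file. No smoothing is applied anywhere.
* No REML, no per-coefficient Wald tests, no threshold-free cluster
  enhancement, no FDR alternative, no spatial regularization of the order
  map — likelihood ratios plus cluster permutation are the single inference
  path.
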