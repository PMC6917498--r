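---
title: "Methods: subtype-stratified connectivity modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype-stratified connectivity modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoconn)
```

# The modeling problem

geoconn implements the statistical pipeline for a question about early-autism
heterogeneity: does splitting ASD toddlers into an eye-tracking-defined
subtype (GeoPref: ≥ 69% of test time fixated on dynamic geometric rather than
social stimuli) explain between-network functional connectivity better than
treating ASD as one group, or than a continuous fixation score? The pipeline
runs from per-subject ICA component time series to edge-wise inference, model
comparison, brain–behavior coupling, motion QC and a design power analysis.

# Connectivity estimation

Per subject, the `T × K` component time-series matrix is demeaned column-wise
and its covariance `C` (denominator `T − 1`) is rescaled by the
root-mean-square of its diagonal. The partial-correlation matrix is read off
the ridge-regularized precision `P = (C + ρI)⁻¹` as
`r_ij = −p_ij / √(p_ii p_jj)`, diagonal set to 0 (it is never analyzed), then
Fisher-transformed.

Choices that matter:

* **ρ = 1** (default): the convention of the reference network-matrix
  toolboxes for short, noisy series. Ridge shrinks edges toward zero
  (roughly halving magnitudes at `ρ = 1` with normalized covariance), which
  stabilizes estimates but means absolute edge values are not comparable
  across different ρ.
* **Covariance normalization** (default on): without it, `ρ = 1` penalizes
  subjects with larger signal scale more strongly. With it, ridge partial
  correlations are invariant to rescaling a subject's data. A flag disables
  it for oracle comparisons; as `ρ → 0` the estimate equals the unregularized
  partial correlation from explicit inversion either way (tested to 1e−6).
* **Plain `arctanh`** for the Fisher transformation. Some toolboxes apply an
  additional empirical rescaling of z values afterwards; this package does
  not, since every downstream statistic is invariant to a monotone rescaling
  shared by all subjects (a documented divergence).

# Design labelings and edge-wise inference

`build_design()` produces three labelings: case-control (one ASD label;
TD, LD/DD and TD-sibling groups kept separate, not collapsed), subtype
(GeoPref / nonGeo, dropping ASD subjects without eye tracking — on the
default cohort exactly the 31 ASD-noET subjects), and transdiagnostic
(continuous % fixation, no group term). The 69% cutoff is inclusive ("69% or
more"); exclusions are returned explicitly rather than silently discarded.

Edge-wise inference is ordinary least squares with age-at-scan (months,
uncentered — AIC differences are unaffected by centering) and sex (binary
indicator) as covariates. The omnibus statistic compares the full model to
the covariate-only model; on 195 subjects with four groups this is F(3, 189),
on the 164 eye-tracked subjects with five groups F(4, 157). Partial η² is
`SS_group / (SS_group + SS_residual)`. FDR control is Benjamini–Hochberg
across the edge family (all component pairs by default; the family is an
argument because the set of "pairs analyzed" is a judgment call).

Pairwise follow-up on surviving edges uses **Freedman–Lane permutation**: the
edge is residualized on the covariates under the reduced model, residuals are
permuted and added back to the reduced fit, and the full model is refit; the
statistic is the adjusted group coefficient. This scheme preserves covariate
structure and is the standard choice where the analysis plan says only
"permutation tests". P-values are two-sided with the add-one convention, so
the smallest attainable p is `1/(n_perm + 1)`; pairwise p-values form their
own FDR family within each surviving edge.

# Model comparison

AIC uses the full Gaussian log-likelihood with σ² counted as a parameter,

`AIC = n[ln(2π) + ln(RSS/n) + 1] + 2(k + 1)`,

matching `stats::AIC()` on the same fit, so values are comparable to those of
any analysis environment using that convention. ΔAIC support bands: ≤ 2
"equivalent"; [4, 7] "considerably less support"; > 7 "essentially none";
(2, 4) labeled "intermediate" because the standard rule of thumb defines
only the first two bands.

Cross-validated MAPE uses 5 folds by default. Folds are random but
**stratified by the finest design labeling and reused bit-identically across
all schemes in one comparison** — both choices are configurable because
either decision (pure random vs stratified; shared vs per-model folds) is
defensible; stratification guarantees every group appears in every training
split, and shared folds remove fold-assignment noise from the model
contrast. Held-out terms with actual value exactly 0 are undefined under the
MAPE formula and are excluded with a logged count (with continuous Fisher-z
edges an exact zero has probability ~0). Because edge values sit near zero,
MAPE magnitudes well above 100% are expected; only differences between
models are interpretable, reported in percentage points.

All schemes in one comparison are fitted to the **identical subject set**
(anyone lacking eye tracking is dropped from every scheme whenever any
scheme needs it); comparing AICs across different subject sets is refused as
a hard error.

# Brain–behavior coupling

The association between an edge and ADOS social affect, controlling age, is
a robust-regression partial correlation: IRLS with the Tukey bisquare weight
(tuning 4.685, 95% Gaussian efficiency), OLS start, MAD-based scale
re-estimated each iteration, convergence when the largest coefficient change
drops below 1e−8 (cap 50 iterations; non-convergence is flagged, the last
iterate returned). The partial correlation is the t-to-r conversion
`r = sign(b)·√(t²/(t² + df))` with `df = n − predictors − 1` and no robust
df correction — the convention of the widely used robust-regression toolbox
this analysis style comes from. This conversion inherits a small upward bias
in |r| at small n relative to the plain sample correlation; the bootstrap
interval, not the point estimate, is the primary inferential object.

Confidence intervals are **percentile bootstrap** over subject-level
resamples (default 100,000; the percentile interval is chosen as the least
assumption-laden of the common bootstrap intervals). Degenerate resamples (constant edge or behavior) are redrawn with
a logged count. Between-subtype differences in correlation strength use the
Fisher-z test `z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3))`.

# Power analysis

The unbalanced two-sample design (16 vs 55) is characterized two ways:
a Monte-Carlo simulation drawing `n₁` values from `Normal(d, 1)` and `n₂`
from `Normal(0, 1)` with a pooled-variance two-sided t-test per experiment,
and a closed-form noncentral-t oracle (noncentrality `d√(n₁n₂/(n₁+n₂))`).
The simulation samples i.i.d. from the infinite population rather than
materializing finite populations of 10 million per group and sampling
without replacement — at 16/55 draws the two are statistically
indistinguishable and the finite population would cost memory for nothing.
`min_detectable_d()` bisects the oracle to |power − target| < 1e−6.

# Motion QC

Framewise displacement per transition is the sum of absolute backward
differences of the three translations plus the three rotations converted to
arc length on a 50 mm sphere (the convention of the FD literature; the
radius is an argument, and a degrees flag converts rotations on read).
DVARS is the RMS backward difference of whatever multivariate signal is
supplied — component time series here, since this pipeline carries no voxel
data (a documented divergence from the voxelwise original). Group balance of
both metrics is tested by one-way ANOVA.

# The synthetic cohort generator

`cohort_config()` defaults define the study conditions: 195 toddlers in six
groups (GeoPref ASD 16, nonGeo ASD 62, ASD-noET 31, LD/DD 15, TD ASDSib 16,
TD 55), 150 volumes at TR 2.5 s, and K = 6 labeled components (DMN, OTC,
PVC, DAN plus two filler components) — smaller than the 30-component
decomposition typical of real analyses, keeping the analyzed networks while
making many-replicate testing cheap.

**Time-series law.** Each group's precision matrix has unit diagonal and
off-diagonal `−r` at planted edges, so the implied partial correlation
equals the target exactly; positive definiteness is enforced by shrinking
off-diagonals (reject-and-shrink). Subject time series follow a stationary
AR(1) process (φ = 0.3, a typical serial correlation at this TR) whose
innovation covariance is `(1 − φ²)Σ`, making the stationary precision equal
the generating precision — `true_edge_values()` is therefore an exact
oracle, not an approximation. Σ is rescaled to unit stationary variance per
component; partial correlations are scale-invariant, so the oracle is
untouched while signal amplitude (and hence DVARS) stays comparable across
groups.

**Planted effects.** Default targets: DMN-OTC 0.30 in TD/TD-sibling (0.28
LD/DD), 0.17 in nonGeo and ASD-noET, and 0.02 in GeoPref — a marked
subtype-specific deficit; DMN-PVC and DMN-DAN carry uniform ASD deficits
(0.14 and 0.12 vs 0.26–0.28 and 0.20–0.22). Published analyses of this design report directions and standardized
effect sizes rather than raw group edge means, so these magnitudes are
chosen once as typical of ridge-regularized netmats; between-subject SD
of the true edge is 0.12 for the same reason. ADOS social affect
(mean 14, SD 4, integer-rounded, ASD groups only) is linear in the subject's
true DMN-OTC edge in GeoPref only, with noise calibrated so the correlation
with the true edge is −0.78; the correlation observable through estimated
edges is attenuated by estimation noise (by design — the same attenuation
affects real data).

**Other variables.** Fixation percentages are truncated normals per group
with subtype membership enforced by rejection sampling around the 69 cutoff
(GeoPref mean 80 SD 8; nonGeo 40/15; comparison groups 30–35) — the
within-subtype distributions are not published, so these are placeholders
with the right support, not estimates. Ages are uniform on 12–48 months. Sex
follows the per-group male fractions of the emulated design. Motion traces are
random walks whose expected mean FD equals the group's target level
(0.06–0.10 mm, typical of sleeping-toddler scans), with lognormal
subject-to-subject spread (sdlog 0.83, CV ≈ 1, the dispersion such cohorts
show) so that group differences in mean motion stay statistically
unremarkable.

**What the generator does not emulate:** volumetric data and spatial ICA
(time series are generated directly at the post-dual-regression stage),
scanner drift and physiological noise, motion-connectivity coupling,
age-connectivity relationships, non-Gaussian behavior distributions, and
missing-at-random eye tracking (ASD-noET is missing by construction).
Passing recovery tests therefore demonstrates correctness of the statistical
machinery under the assumed data-generating process, not robustness to every
artifact of real rsfMRI.

# Numerical and degenerate-input policy

Constant time-series columns, non-finite inputs, asymmetric matrices (beyond
1e−10), rank-deficient designs, zero pooled SDs, zero-margin contingency
tables and `|r| ≥ 1` are all rejected with specific errors rather than
propagated. Every stochastic function takes an explicit seed and restores
the caller's RNG state, so pipelines are reproducible stage by stage;
`run_all()` derives per-stage substreams from one global seed and rerunning
an identical configuration reproduces every output byte-identically.

# Problem sizes used by the test suite

The suite favors many small replicates over single large runs: calibration
of estimated edges against the precision oracle uses 100 replicate cohorts
at T = 4000 with ρ → 0; permutation type-I error uses 1000 null simulations
at 500 permutations; model-selection recovery uses 50 replicate cohorts at
the full 195-subject design (both for a subtype-specific deficit with a
realized standardized gap near 0.9, and for a uniform ASD deficit where
parsimony should favor case-control); brain-behavior recovery uses 20
replicate 16 + 62 cohorts with 2000-resample bootstraps; bootstrap coverage
uses 200 replicates of n = 100 at 5000 resamples. These sizes make the full
suite run in a few minutes while leaving Monte-Carlo error well inside the
asserted bands.

# Known limitations

* Absolute AIC and MAPE values depend on the data; only the comparative
  machinery is validated against published worked examples (ΔAIC pairs, the
  MAPE difference, the chi-square, the power-analysis quantities).
* The t-to-r robust correlation is a convention, not an unbiased estimator;
  at n = 16 its point estimate can exceed the generating correlation.
* The Fisher-z test for comparing correlations assumes independent groups
  and normal sampling of z — adequate here, but approximate for robust
  correlation estimates at small n.
* The generator's AR(1)-with-known-precision law makes oracles exact at the
  price of realism; it is a test harness, not a simulator of fMRI physics.
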