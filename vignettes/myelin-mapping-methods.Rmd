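---
title: "Methods: longitudinal intracortical myelin mapping with myelinmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal intracortical myelin mapping with myelinmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelinmap)
```

## The measurement model

T1-weighted MRI intensity rises with myelin content and T2-weighted
intensity falls with it, so their voxelwise ratio `R = T1/T2` amplifies
myelin contrast while cancelling multiplicative nuisance fields shared by
the two acquisitions. `myelinmap` takes co-registered, bias-corrected T1 and
T2 volumes as given (bias-field correction and registration are upstream
tools' business, declared by contract) and computes `R` only where the
denominator is trustworthy: voxels with T2 at or below a floor `epsilon` are
marked *invalid* rather than given a number. The floor defaults to
`1e-6` times the 99th percentile of valid T2 intensities — a relative rule,
because scanner intensity units are arbitrary. Invalid voxels propagate as
missing through all later stages; zero-filling them would bias
length-weighted averages downward. No physiological clipping of `R` is
applied before averaging.

## Transcortical sampling

The cortical ribbon is bounded by the white (GM/WM interface) and pial
surfaces, represented as triangle meshes with 1:1 vertex correspondence.
Each white vertex is joined to its paired pial vertex by a straight
*transcortical segment*; the vertex's `R` value is the average of the
gray-matter voxels the segment traverses, each weighted by the length of
the segment inside that voxel.

Three numerical choices matter here:

* **Coordinates.** Everything is world millimetres; voxel space is entered
  only inside the traversal, through the inverse affine. A voxel `(i,j,k)`
  (0-based) spans the half-open cube `[i, i+1)` in continuous voxel
  coordinates, so a boundary crossing belongs deterministically to the
  entering voxel and no length is counted twice.
* **Traversal.** In-voxel lengths come from exact plane-crossing
  computation (all integer-plane intersections of the parametrized segment,
  sorted; cell of each interval identified by its midpoint). The lengths
  telescope, so they sum to the segment length to floating-point precision;
  the test suite bounds the error at `1e-9` mm and cross-checks values
  against a 10^4-point dense-sampling oracle.
* **Pairing.** Vertex correspondence defaults to index identity
  (`search_ring = 0`), which is how FreeSurfer-style surface pairs are
  indexed. An optional `search_ring = k` refinement re-pairs each white
  vertex with the *nearest* pial vertex inside the k-ring mesh
  neighbourhood of its corresponding vertex — the neighbourhood restriction
  is the topological constraint that keeps pairs from jumping across a
  sulcus. Ties resolve to the lowest vertex index. The choice is logged in
  the pipeline's provenance output.

Non-GM and invalid voxels are excluded from the weighted average and the
weight renormalizes over the remaining length; a vertex whose segment meets
no valid GM voxel is *missing*, and missing vertices are excluded from
parcel means rather than imputed. Segment length doubles as a simple
thickness measure, and `normalize_by_icv()` provides the conventional
head-size normalization for regional volumes.

Regional aggregation for group maps follows a fixed order: average over the
subjects of a group at each vertex first, then over the vertices of each
parcel. Subject-level statistics instead use each subject's own regional
means (the `subject_region` output), so within-subject change is never
computed from group-averaged maps.

## Longitudinal statistics

Each subject is scanned twice, with the interscan interval (ISI) differing
systematically between groups (healthy controls ~3.3 y; mTBI ~0.5 y). The
within-subject analysis proceeds per region:

1. Baseline and follow-up values are adjusted for age and sex by OLS
   residualization plus restoration of the grand mean. ISI is deliberately
   *not* a confound here — it carries the longitudinal signal. Adjustment is
   fitted within each diagnostic group, so group differences are not
   absorbed into the confound fit (the groups come from different studies
   with different age ranges, and a pooled fit would alias diagnosis with
   age).
2. The fractional change `ΔR = (R_f − R_b)/R_b` is computed per subject and
   rescaled linearly (`ΔR × target/ISI`, a constant-rate assumption) to a
   common target interval, by default the mTBI group's mean ISI. Both
   native and rescaled group means are reported, since either convention is
   defensible for the slow-changing control group.
3. Welch's two-sided t test compares rescaled `ΔR` between groups per
   region; Holm's step-down correction controls the family-wise error rate
   across regions. Holm is the default because it is uniformly more
   powerful than Bonferroni at identical guarantees; Bonferroni is
   available behind the `correction` argument. Paired t tests of baseline
   versus follow-up within group are reported alongside.
4. Regional *vulnerability* is the leave-one-out contrast
   `v_r = [u(ΔR_r) − u(ΔR_S)]/u(ΔR_S)`: with losses (negative changes), a
   positive `v` means proportionally more demyelination than the rest of
   the cortex. Leave-one-out means are computed by exact arithmetic; a zero
   leave-one-out mean leaves `v` undefined and flagged.
5. The acute baseline contrast `Δz` standardizes each observation against
   its own group's pooled mean and sd (over subjects and regions) before
   differencing per-region group means. Pooling over regions is what makes
   the contrast informative: standardizing each region separately across
   subjects would force every group-region mean z to zero and `Δz` to
   vanish identically. The pooled form keeps the intended property — any
   affine intensity rescaling of one group cancels — while measuring how a
   region's standing within its group's cortical distribution differs
   between groups.

### The mixed model

Group-by-time effects are modelled as `y = Xβ + Zu + ε` with fixed effects
intercept, diagnosis, age, sex, scanner and age x sex (age powers up to 4
are available behind `age_powers`; the default is linear, matching the
selected model), and per-subject random intercepts and slopes on
`Δt = u(t) − t_i`, the deviation of the subject's ISI from the grand mean
across *both* groups. Grand-mean (not group-mean) centering is essential:
group-wise centering would absorb part of the diagnosis-by-time interaction
into the random effects. `Δt` is zero at baseline and sums to zero over
follow-up observations.

Fitting is by maximum likelihood (not REML, so likelihood-ratio comparisons
of fixed effects are valid), delegated to `lme4` with a triangular
(Cholesky) covariance parameterization, step tolerance `1e-12` and an
iteration cap of `1e5`. Random intercept and slope are independent by
default, mirroring separate `N(0, σ0²)` and `N(0, σ1²)` priors; a correlated
pair sits behind `correlated = TRUE` (with two observations per subject this
doubles the random-effect count to the observation count, so the
dimensionality guards are relaxed — the likelihood remains proper).
`converged` requires both a clean optimizer exit and positive
(semi-)definite curvature at the optimum; a variance component legitimately
estimated on the boundary (zero) is not treated as failure. The test suite
cross-checks the maximized likelihood against a direct marginal-Gaussian
evaluation and verifies `AIC = 2k − 2logL` and the BIC identity.

`compare_models()` performs the likelihood-ratio test between nested ML
fits (statistic clamped at zero, chi-square reference with the
parameter-count difference as df) and reports AIC/BIC for both models. The
model can be fitted to cortex-wide mean `R` (default `lmm_table()`) or per
region (`region = ...`); both modes are supported because regional and
global analyses answer different questions.

### Age sensitivity and cognition

`age_overlap_subset()` implements the sensitivity analysis for the groups'
disjoint-ish age ranges: controls younger than the oldest mTBI subject and
mTBI subjects older than the youngest control are retained (strict
inequalities), and the downstream analysis reruns unchanged on the subset.

Cognitive scores (six tests: EVMI, EVMD, WMS, VF, IR, PS) standardize
against reference norms as `z = (x − μ)/σ`; norms are inputs, not shipped
constants, because normative values belong to their cohort. Associations
with myelin measures use Spearman's rank correlation (scores are not
normally distributed): the exact null distribution for n ≤ 10 without ties,
the t approximation otherwise. Because the scores are intercorrelated, the
Benjamini–Yekutieli procedure — valid under arbitrary dependence via the
harmonic-sum penalty `c(m) = Σ 1/i` — controls the false discovery rate.
The multiplicity family is configurable (whole battery versus per-timepoint
blocks) because the right family depends on the analysis plan, not the
software.

## The synthetic cohort generator

Clinical MRI with linked diagnoses is restricted data, so validation runs
on synthetic inputs whose ground truth is known exactly. The generator has
two fidelity levels:

* **Region fidelity** (fast path): longitudinal tables of regional `R`.
  True follow-up is `baseline × (1 − rate × mult × ISI)` — linear-in-time
  decline, matching the constant-rate assumption of the analysis — where
  `rate` is the group/region decline and `mult ~ N(1, subject_random_sd²)`
  a per-subject multiplier. Additive `N(0, measurement_sd²)` noise lands on
  each observed visit; an optional shared component induces within-subject
  correlation of regional noise (its true value is unknown, so it is a
  knob, default 0). Age and sex effects (default off) scale the biological
  signal; the scanner factor scales the *measured* value, as an
  instrumental effect should.
* **Image fidelity** (slow path): per-subject, per-visit phantom volumes.
  The phantom is a spherical shell — white and pial spheres from a
  subdivided icosahedron, parcellated into equal azimuthal sectors — which
  is enough to exercise pairing, traversal and parcel statistics while
  keeping every geometric truth closed-form. Folding, scanner physics and
  realistic bias fields are out of scope. Intensity noise is multiplicative
  log-normal applied independently to T1 and T2 (mean factor 1), so
  intensities stay positive and the noisy ratio remains log-normal and
  analytically checkable.

Default conditions are the study conditions: 80 controls versus 97 mTBI
subjects; ages 60–90 y (mean 75.4) and 19–79 y (mean 43.1); male fractions
0.53/0.63; mean ISIs 3.3 y and 0.5 y; 70 of 80 controls on a GE scanner,
everyone else Siemens (coded 0 = Siemens, 1 = GE; diagnosis 0 = HC,
1 = mTBI; sex 0/1). Where only a mean is printed for a quantity, the spread
was chosen once at a realistic scale: ISI sd 0.8 y for controls (naturalistic
revisit spacing) and 0.1 y for the protocolized half-year follow-up; age sds
7 y and 15 y consistent with the printed ranges. The decline conditions are
2%/yr for controls and 20% per half-year for mTBI, with the occipital pole
injected at 22% below the other regions as the designated low-vulnerability
region; baseline ratios anchor to printed control values from the most
(inferior occipital, 1.25) to the least (temporal pole, 0.96) myelinated
region. `subject_random_sd = 0.13` and `measurement_sd = 0.005` put the
spread of observed changes at a few percent, the scale reported for such
cohorts. All randomness flows through one seeded generator consumed in a
fixed subject order, so a seed fixes the cohort byte-for-byte.

What passing tests do *not* show about real data: the phantom has no
gyrification, so partial-volume behaviour in tight sulci is unexercised; the
generator's decline is exactly linear, so the rescaling step is exact by
construction rather than approximately right; and measurement noise is
Gaussian and mostly independent across regions, which flatters the
calibration of region-wise tests relative to spatially correlated real
noise (the `region_noise_cor` knob exists precisely to probe that).

## Problem sizes and tolerances

The shipped validation uses an icosphere at subdivision 3 (642 vertices,
1,280 triangles) in a 64³ grid of 2 mm voxels for phantom recovery (regional
means within 1% of truth; the tolerance covers partial-volume voxels at
shell and sector borders), 1,000 random segments for traversal conservation
(`1e-9` mm) and dense-oracle agreement (`1e-3` relative), 50 replicate
cohorts of 40 + 40 subjects for injected-effect recovery (within 2
Monte-Carlo standard errors), 500 replicates of 100 subjects for
likelihood-ratio null calibration (rejection rate in [0.03, 0.07]) and 500
replicates of 74 null regions for family-wise control. Statistic identities
(fractional change, rescaling, vulnerability, z-scores, Benjamini–Yekutieli
thresholds, Holm) are checked at `1e-12` against hand-computed values.

## Known limitations

* Surface reconstruction, inter-subject surface registration and bias-field
  correction are consumed, not produced; synthetic subjects share the
  template mesh by construction.
* The "topological constraints" appropriate for vertex pairing on real,
  folded surfaces are not uniquely defined; both pairing modes are provided
  and recorded, but neither is validated against folded geometry.
* Whether GM-labelled voxels partially outside the ribbon should be
  down-weighted is unresolved; full in-voxel length weighting is used.
* FreeSurfer binary surface and annotation formats are not parsed; surfaces
  and parcellations travel as ASCII PLY and CSV.
* The mixed model inherits lme4's behaviour for boundary fits; with two
  visits per subject the random-slope variance is weakly identified, which
  is faithful to the design but means `sigma1_sq` estimates are noisy.
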