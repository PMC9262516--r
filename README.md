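# myelinmap

Longitudinal intracortical myelin mapping from T1-weighted/T2-weighted MRI
intensity ratios, in R.

## The problem

The ratio *R* of T1-weighted to T2-weighted MRI intensity is a practical
in-vivo proxy for relative intracortical myelin content: both modalities'
sensitivities to myelin point the same way once their ratio cancels shared
nuisance fields. `myelinmap` implements the full chain needed to study how
*R* changes over time in two diagnostic groups — typically healthy controls
(HC) followed over years and mild-traumatic-brain-injury (mTBI) patients
rescanned about six months after injury:

1. **Voxel ratio** — `compute_ratio_volume()` forms `R = T1/T2` wherever the
   denominator is trustworthy, and `mask_to_gm()` restricts it to gray
   matter.
2. **Surface sampling** — `pair_vertices()` joins corresponding white and
   pial mesh vertices by transcortical segments; `trace_segment_voxels()`
   marches each segment through the voxel grid by exact plane crossings; and
   `sample_vertex_ratio()` assigns each white-surface vertex the
   length-weighted average of the gray-matter voxels its segment traverses.
3. **Regional aggregation** — `vertex_map_to_regions()` averages over
   subjects at each vertex, then over the vertices of each parcel.
4. **Longitudinal statistics** — per subject and region the fractional
   change `ΔR = (R_f − R_b)/R_b` is computed from age/sex-adjusted values
   (`adjust_for_confounds()`), rescaled linearly to a common interscan
   interval (`rescale_delta_linear()`), compared across groups with Welch's
   t test under Holm correction, and summarized by leave-one-out regional
   vulnerability `v = [u(ΔR_r) − u(ΔR_S)]/u(ΔR_S)` and the group-standardized
   baseline contrast `Δz = z_TBI − z_HC`. A mixed model
   `y = Xβ + Zu + ε` with per-subject random intercepts and slopes on the
   ISI deviation `Δt = u(t) − t_i` (`fit_lmm()`, via maximum likelihood)
   tests the diagnosis effect by likelihood ratio (`compare_models()`).
5. **Cognition** — `spearman_correlation()` and `by_fdr()` relate regional
   myelin measures to six cognitive scores under Benjamini–Yekutieli FDR
   control; raw scores standardize against reference norms with
   `zscore_against_reference()`.

Because the underlying clinical MRI data are restricted, the package ships a
first-class synthetic-data module: `make_template_geometry()` and
`make_intensity_volumes()` build spherical-shell cortex phantoms with known
regional ratios, and `make_longitudinal_cohort()` generates two-group
longitudinal cohorts with known decline rates, demographics and noise, so
every pipeline stage can be validated against ground truth.

## Worked example

```r
library(myelinmap)

# a cohort emulating the study conditions: 80 HC (mean ISI 3.3 y),
# 97 mTBI (mean ISI 0.5 y), HC losing 2%/yr and mTBI 20% per half-year,
# with the occipital pole injected 22% below the other regions
sim <- make_longitudinal_cohort(cohort_config(seed = 1))
st  <- region_stats(sim$cohort, target_isi_years = 0.5)
out <- st[, c("region_name", "delta_r_hc_rescaled", "delta_r_tbi_rescaled",
              "diff", "v_tbi")]
out[, 2:5] <- round(out[, 2:5], 4)
as.data.frame(out)
```

```
                   region_name delta_r_hc_rescaled delta_r_tbi_rescaled    diff   v_tbi
1           inferior_occipital             -0.0101              -0.1998 -0.1897  0.0351
2 anterior_transverse_temporal             -0.0099              -0.1994 -0.1895  0.0327
3               occipital_pole             -0.0099              -0.1555 -0.1456 -0.2201
4       transverse_frontopolar             -0.0098              -0.1996 -0.1898  0.0339
5                   subcentral             -0.0100              -0.2000 -0.1900  0.0359
6                   precentral             -0.0099              -0.1998 -0.1899  0.0346
7   posterior_dorsal_cingulate             -0.0100              -0.1985 -0.1885  0.0270
8                temporal_pole             -0.0100              -0.1986 -0.1886  0.0281
```

Reading: over the mTBI group's mean half-year interval, controls lose about
1% of cortical *R* while mTBI subjects lose about 20% — a difference of
roughly −19 percentage points — and the occipital pole, injected with 22%
less decline than the rest of the cortex, is recovered with vulnerability
`v ≈ −0.22` (22% *less* demyelination than the other regions). All eight
regions separate between groups after Holm correction (`st$significant`).

The mixed model on the same cohort:

```r
tab <- lmm_table(sim$cohort)
summary(fit_lmm(tab))
compare_models(fit_lmm(tab), fit_lmm(tab, include_diagnosis = FALSE))$p_value
```

`run_pipeline(run_config(out_dir = "out", seed = 1))` executes the whole
chain and writes `cohort.csv`, `region_statistics.csv`, `lmm_report.json`,
`cognition_correlations.csv` and `provenance.json`; runs with identical
seeds are byte-identical.

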