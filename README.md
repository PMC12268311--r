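# tilzone

Spatial quantification and prognostic modelling of tumor-infiltrating
lymphocytes (TILs) from classified-nuclei point clouds.

## What it is for

Deep-learning pipelines for H&E whole-slide images routinely emit a table
of nuclei — centroid coordinates plus a class (tumor / lymphocyte / other).
For tumors such as esophageal squamous cell carcinoma, the prognostic
signal of lymphocytes depends on where they sit relative to the tumor
margin. `tilzone` takes such a nuclei table and produces patient-level
survival inference:

- **Tumor region**: rasterize tumor centroids (default 4 µm cells),
  morphological closing (50 µm disk), hole filling, 8-connected components
  with a minimum-area filter.
- **Zones**: Euclidean distance transform of the tumor complement;
  intratumor, peritumoral (distance *d* with 0 < *d* ≤ 300 µm, closed
  above), stromal (*d* > 300 µm). Lymphocytes become **I-TILs**,
  **P-TILs**, **S-TILs**; counts satisfy `total = I + P + S` by
  construction.
- **Cutoffs**: minimum-p scan of maximally selected log-rank statistics
  over the distinct marker values in the 10–90% quantile window, with the
  Miller–Siegmund correction for selection optimism
  (`scan_cutpoints()`) — the X-tile idea as a testable function.
- **Stratification**: HIGH iff I-TILs > c_i **and** P-TILs > c_p (strict).
- **Inference**: Kaplan–Meier with Greenwood variance and log-log CIs,
  log-rank test, Cox proportional hazards (Efron ties), logistic
  propensity scores with greedy 1:1 caliper matching (0.2 SD of the logit)
  and SMD balance diagnostics, per-stratum hazard-ratio tables.
- **Synthetic data**: seeded generators for slides (disk tumor nests,
  region-dependent Poisson lymphocytes, exact analytic ground truth) and
  cohorts (log-normal counts moment-matched to published means/SDs,
  exponential survival calibrated to published group-specific 5-year OS of
  67.9% / 54.4%, hence a closed-form true hazard ratio
  `ln(0.679)/ln(0.544) = 0.636`).

## Worked example

```r
library(tilzone)

# a synthetic slide with known truth, then the raster pipeline
sim   <- simulate_slide(slide_sim_params(seed = 7))
mask  <- build_tumor_mask(sim$slide)
zones <- label_regions(mask)
slide <- assign_nuclei_regions(sim$slide, zones)
count_tils(slide, zones)
#> <til_profile> patient sim7: I=2731 P=3780 S=4730 total=11241

# a synthetic 596-patient cohort, stratified at fixed cutoffs
coh <- simulate_cohort(cohort_sim_params(seed = 11))
til_prognosis(coh$cohort, coh$profiles,
              cutoffs = joint_cutoffs(9377, 9483), seed = 3)
#> <til_prognosis> outcome OS, n = 596 (HIGH 191 / LOW 405)
#>   joint rule: i_tils > 9377 & p_tils > 9483 (fixed)
#>   log-rank: chi2 = 8.18, p = 0.00424
#>   adjusted HR (HIGH vs LOW): 0.613 (95% CI 0.435-0.865, p = 0.00535)
#>   after matching (191 pairs): log-rank p = 0.0047, HR 0.578 (0.394-0.849)
```

Reading the output: 191 of 596 simulated patients jointly exceed both
count cutoffs; their hazard of death is estimated at ~0.6 of the LOW
group's after covariate adjustment (the generator's true value is 0.636),
and the effect survives 1:1 propensity matching. On real data, replace the
simulated inputs with `read_nuclei()` / `read_cohort()` tables and leave
`cutoffs = NULL` to derive them by the minimum-p scan.

The methods vignette (`vignettes/til-spatial-survival.Rmd`) documents the
model, parameter defaults, simulator calibration and limitations.

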