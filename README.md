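# rsiscope

Automated patient-level detection of clinically significant prostate cancer
(csPCa, histologic grade group ≥ 2) from multi-b-value diffusion-weighted
MRI, with no lesion delineation: each patient's prostate is reduced to a
single quantitative number and compared against the radiologist's ordinal
PI-RADS score.

The package implements, in R:

* **Four-compartment diffusion decay model.** After scaling by the median
  b = 0 signal in the prostate, the per-voxel signal is fit as
  S(b) = Σᵢ Cᵢ·exp(−b·Dᵢ) with fixed coefficients
  D = (1.0e−4, 1.8e−3, 3.6e−3, ≫3e−3) mm²/s (restricted, hindered, free,
  vascular flow) by exact nonnegative least squares. The fitted C₁ map is
  the **RSI restriction score**, a per-voxel cancer biomarker.
* **Conventional ADC maps** from b-value subsets (vendor-style 0/1000 and
  alternate 0/500/1000), as the negative log-linear OLS slope.
* **Patient-level reduction**: maximum restriction score and minimum ADC
  over the prostate contour expanded by a uniform 5-mm margin (millimetric
  dilation honoring anisotropic voxels), whole-gland or zone-restricted.
* **Detection statistics**: midrank ROC/AUC, paired-bootstrap confidence
  intervals and two-sided p-values (10 000 resamples), within–PI-RADS-
  stratum logistic posteriors concatenated into a combined
  PI-RADS + restriction-score ROC, and per-category detection-rate tables.
* **A seeded synthetic DWI cohort generator** (ellipsoidal gland and zones,
  tissue archetypes, grade-modulated lesions, Rician noise, PI-RADS
  calibrated to published per-category biopsy counts) so the whole analysis
  runs end to end without clinical data.

## Worked example

```r
library(rsiscope)

res <- run_all(run_config(n_boot = 2000, seed = 17))
results_table(res)[1, c("analysis", "n", "adc_vendor_auc", "rsirs_auc",
                        "pirads_auc", "combined_auc")]
#>   analysis   n adc_vendor_auc rsirs_auc pirads_auc combined_auc
#> 1    whole 151      0.4583629 0.9169029  0.8334515    0.9271793

res$detection_rates
#>   pirads n_negative n_positive rate_percent
#> 1      1          0          0           NA
#> 2      2          0          2        100.0
#> 3      3         20          0          0.0
#> 4      4         40         20         33.3
#> 5      5          8         61         88.4
```

The row reads: on the default 151-patient synthetic cohort, automated
minimum ADC is at chance (AUC 0.46 — the margin-expanded search is dominated
by near-noise-floor extraprostatic voxels), the maximum restriction score is
strongly informative (0.92), PI-RADS performs as calibrated (0.83), and the
stratified PI-RADS + restriction-score combination improves on PI-RADS
alone (0.93). The detection-rate table shows the per-category csPCa rates of
the sampled cohort (e.g. 88.4% of PI-RADS 5 patients).

Individual stages are exposed directly: `simulate_patient()` /
`simulate_cohort()`, `normalize_by_median_b0()`, `fit_compartments()`,
`compute_rsirs()`, `fit_adc()`, `expand_mask()`, `reduce_patient()`,
`auc()`, `bootstrap_compare()`, `stratified_posteriors()`,
`detection_rate_table()`, with NIfTI-1 input/output via
`write_patient_nifti()` / `read_dwi_nifti()` and a thin CLI at
`inst/scripts/rsiscope.R`. The methods vignette
(`vignettes/rsiscope-methods.Rmd`) documents the model, the simulator's
assumptions and its limits.

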