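# drusevol

Comparability of automated drusen volume measurements across OCT
devices and scan patterns.

Drusen — deposits between the retinal pigment epithelium (RPE) and
Bruch's membrane (BM) — define early and intermediate age-related
macular degeneration (AMD), and their OCT-derived volume is a promising
structural endpoint. But volumes from different devices, segmentation
algorithms and B-scan densities are **not interchangeable**: algorithms
differ systematically, sparse scans miss medium drusen, and reticular
pseudodrusen (RPD) are segmented inconsistently. `drusevol` is a
simulation and analysis toolkit for quantifying exactly how much, for
researchers comparing drusen quantification pipelines or planning
multi-device studies.

The package provides:

* **Synthetic cohorts with analytic truth** — eyes with spherical-cap
  drusen on a smooth BM baseline (cap volume
  `V = πh/6 · (3a² + h²)`), staged by the Beckmann maximum-diameter
  classes (≤63 / 63–125 / >125 µm), with optional RPD lesions and
  device profiles that emulate scan geometry, surface noise, systematic
  drusen-height bias and stochastic RPD capture.
* **Two drusen segmentation strategies** — a healthy-RPE floor at a
  per-eye BM offset (histogram-mode estimate), and an iteratively
  refitted per-B-scan expected-RPE polynomial — plus the 5-pixel
  (19.5 µm) en-face connected-component filter for small false-positive
  elevations.
* **Volumetry** — slow-axis interpolation of the filtered height map
  and drusen volume inside fovea-centered 3- and 5-mm circles.
* **The full method-agreement analysis** — two-way ICC (consistency
  and agreement, with F-based confidence intervals), Bland–Altman
  summaries with standardized mean differences, paired Wilcoxon and
  Jonckheere–Terpstra tests with exact small-sample branches, ROC
  threshold selection by `min((1−se)² + (1−sp)²)`, high-risk cut-off
  agreement (Cohen's kappa), and Deming (λ = 1) conversion formulae
  with optimal-subset selection and seeded 80/20 train/test evaluation.

## Worked example

A cube-scan high-progression-risk cut-off of 0.03 mm³ converts to the
dense raster scale with the published Deming line:

```r
library(drusevol)
conv <- reference_conversion()
round(apply_fit(conv$cirrus_to_spectralis, 0.03), 3)
#> [1] 0.083
```

A small end-to-end study — simulate a cohort, measure every eye with
its device's algorithm, and compare methods:

```r
cfg <- study_config(sim = sim_cohort_config(
  n_per_stage = c(no_amd = 10, eamd = 10, iamd = 30), seed = 7))
bundle <- run_study(cfg)

dplyr::filter(bundle$agreement, subgroup == "iamd")[,
  c("comparison", "n", "icc_consistency", "icc_agreement",
    "mean_diff", "std_mean_diff", "rmse")]
#>     comparison  n icc_consistency icc_agreement mean_diff std_mean_diff    rmse
#> 1 inter_device 30           0.739         0.383  0.044544       0.71272 0.05017
#> 2   inter_scan 30           0.986         0.986  0.000811       0.00962 0.00684
```

The two scan densities of the same (unbiased) algorithm agree almost
perfectly in iAMD, while the biased cube-scan algorithm shows a large
systematic difference — about 71 % of the mean measured volume — that
penalizes agreement-type ICC far more than consistency-type. Medium
drusen tell the detection story:

```r
dplyr::summarise(
  dplyr::group_by(dplyr::filter(bundle$measurements, stage == "eamd"), method),
  detected = mean(volume_5mm_mm3 > 0))
#>              method detected
#> 1            cirrus      0.3
#> 2  spectralis_dense      1.0
#> 3 spectralis_sparse      0.6
```

and the fitted inter-device conversion recovers the simulated bias:

```r
glance(bundle$conversion$fits$spectralis_to_cirrus)
#>   slope intercept lambda     n
#> 1 0.439   0.00283      1    24
```

`write_report(bundle, "out", format = "csv")` serializes the manifest,
measurements, agreement, ROC and conversion tables.

## Documentation

See the vignette `drusen-volume-comparability` for the measurement
model, the statistical methodology, calibration of the synthetic
generator, numerical choices and known limitations.
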