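---
title: "Comparing automated drusen volume measurements across OCT devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing automated drusen volume measurements across OCT devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Drusen — extracellular deposits between the retinal pigment epithelium
(RPE) and Bruch's membrane (BM) — are the hallmark lesion of early and
intermediate age-related macular degeneration (AMD), and their volume on
OCT is a candidate structural endpoint for trials. Different OCT devices
quantify drusen with different proprietary algorithms and different scan
patterns, and the resulting volumes are *not* interchangeable: one
device/algorithm pair can systematically report half the volume of
another, sparse scan patterns can miss medium drusen entirely, and
reticular pseudodrusen (RPD, deposits sitting *above* the RPE) are
captured inconsistently.

`drusevol` makes every stage of that comparison exercisable without
patient data: a synthetic cohort generator with analytic ground truth,
the two published styles of drusen segmentation, fovea-centered circle
volumetry, and the complete agreement / threshold / conversion analysis.

## The measurement model

### Ground truth

An eye consists of

* a smooth BM baseline — a quadratic surface with coefficients of a few
  tens of microns over the scanned field;
* a physiologic BM-to-RPE offset, uniform over the eye, drawn once per
  eye from 30–40 µm;
* drusen modeled as **spherical caps** on the RPE. A cap with base
  radius $a$ and height $h$ has the closed-form volume
  $V = \frac{\pi h}{6}\,(3a^2 + h^2)$, which gives every simulated eye
  an analytic truth volume (`analytic_drusen_volume()`) against which
  measured volumes can be checked. The cap shape is a modeling choice —
  real drusen are irregular — made so that oracles are closed-form;
* optionally, RPD lesions: small caps (~100 µm across) that are added
  *on top of* the RPE, not between BM and RPE.

Stages follow the Beckmann maximum-diameter classes: all drusen ≤ 63 µm
(`no_amd`), largest druse in (63, 125] µm (`eamd`), largest druse
> 125 µm (`iamd`). The generator enforces the class bound by
construction and draws counts and sizes from right-skewed distributions.
The published study reports only per-stage volume summaries, not count
or size distributions, so the defaults in `default_bump_params()` were
calibrated once so that per-stage 5-mm volumes rise across stages by the
reported orders of magnitude (no AMD ≈ 10⁻⁴ mm³ with ~90 % exact zeros,
eAMD ≈ 10⁻³ mm³, iAMD ≈ 10⁻¹ mm³ with strong right skew), and then
frozen.

### Device profiles

A `device_profile()` carries the sampling geometry (B-scan count and
spacing, A-scan pitch, axial pixel pitch) and the measurement
idiosyncrasies the simulator imposes:

* independent Gaussian noise (sd 2 µm) added per node to each surface;
* a linear distortion of drusen height (`bias_slope`,
  `bias_intercept_um`) applied where true drusen are present — the
  default cube-scan profile uses slope 0.5, emulating an algorithm that
  systematically reports roughly half the raster-scan volume;
* a per-lesion Bernoulli capture probability for RPD (`rpd_capture_prob`,
  0.7 for the raster profiles vs 0.3 for the cube profile), the
  mechanism by which RPD degrade inter-device agreement.

The three defaults mirror common macular protocols: 241 B-scans at
30 µm (30°×25°), 25 B-scans at 240 µm (20°×20°), and a 200×200 cube
over ~6×6 mm, with fields expressed directly in microns (~290 µm per
degree) and the nominal 30/240 µm spacings matched by construction.

### Segmentation

Two healthy-RPE floors are implemented:

* **BM-offset** (`floor_from_bm()`): the per-eye offset is estimated as
  the mode of the histogram of `rpe − bm` with a bin width of one axial
  pixel; ties go to the smaller offset and the returned value is the
  median gap inside the modal bin (so a constant gap is recovered
  exactly). Drusen lift the RPE at a minority of nodes and do not move
  the mode.
* **Expected-RPE fit** (`floor_from_rpe_fit()`): per B-scan, a degree-3
  polynomial is fitted to the segmented RPE and iteratively restricted
  (5 iterations) to nodes within 5 µm above the current fit, excluding
  drusen from the support. A quadratic BM baseline restricted to one
  B-scan is quadratic in the fast axis, so the cubic fit reproduces
  drusen-free rows essentially exactly.

Heights are `max(rpe − floor, 0)`. Two cleanups follow:

1. **Minimal elevation**: nodes below one axial pixel (3.9 µm by
   default) are zeroed. Without this, zero-mean surface noise marks
   about half of all nodes as minutely "elevated"; at that density the
   8-connected positive mask percolates, and the resulting
   grid-spanning speckle component inherits the keep decision of every
   true druse it touches, adding a per-eye random volume large enough
   to destroy inter-scan agreement. Device softwares likewise require a
   minimal RPE elevation before calling drusen.
2. **Small-component filter** (`filter_small_components()`): 8-connected
   components of the positive en-face mask whose *peak* height is
   strictly below 5 axial pixels (19.5 µm at the 3.9 µm pitch) are
   removed; a peak of exactly 19.5 µm is kept. The filter is idempotent
   and can only reduce volume. Whether devices filter per B-scan or
   en-face is not documented; en-face was chosen to match the published
   description of components in a drusen en-face projection, and
   8-connectivity matches common image-analysis practice.

### Volumetry

The filtered map is linearly interpolated along the slow (B-scan) axis
onto a common grid (30 µm by default — the finest default spacing), and
volume is summed over en-face nodes whose centers fall inside a
fovea-centered 3- or 5-mm circle (`volume_in_circle()`), with no
partial-pixel weighting: node-center inclusion is simple, testable and
convergent as the grid refines (measured cap volumes are within 2 % of
the closed form at 10 µm spacing).

Interpolating the *filtered map* rather than the raw surfaces is
deliberate: a sparse pattern cannot re-detect drusen between its
B-scans. That is exactly the mechanism behind the key qualitative
finding — large (iAMD) drusen are interpolated well and the two
Spectralis-style patterns agree almost perfectly, while medium (eAMD)
drusen fall between 240-µm-spaced B-scans and are missed. Note the
quantitative limit: a 500-µm dome sampled by only three B-scans
reconstructs ~15 % low no matter how the samples are integrated; good
sparse-scan agreement is a property of large or numerous drusen, not of
any single medium druse.

## The statistics

All agreement statistics are implemented from first principles and
cross-checked in the test suite against independent oracles
(`aov()` mean squares, exhaustive sign/permutation enumeration,
all-pairs AUC counting, `pROC`, base `wilcox.test()`).

* **Two-way ICC** (single measurement): consistency
  $(MS_R - MS_E)/(MS_R + (k-1)MS_E)$ ignores a systematic shift between
  methods; agreement adds $(k/n)\,(MS_C - MS_E)$ (truncated at zero) to
  the denominator and penalizes it. Adding a constant to one method
  provably leaves consistency unchanged and strictly lowers agreement —
  the central statistical point when methods disagree systematically.
  Confidence intervals use the standard F constructions (exact F for
  consistency, Satterthwaite for agreement). Subgroups with no
  between-eye variance return a named `undefined` status rather than a
  number.
* **Bland–Altman**: mean difference, 1.96-sd limits of agreement, and
  the standardized mean difference (mean difference divided by the mean
  of the per-eye averages of the two methods).
* **Wilcoxon signed rank** (zeros dropped, Wilcoxon's original
  treatment): exact null by convolution over sign flips up to 25
  nonzero differences (valid under midrank ties), normal approximation
  with tie and continuity correction above.
* **Jonckheere–Terpstra** for ordered stage trends: exact permutation
  null by exhaustive enumeration up to n = 10, tie-corrected normal
  approximation (no continuity correction) above.
* **ROC**: candidate thresholds at observed values (positive at ≥
  threshold), AUC from the rank statistic with half-weight ties, and
  threshold selection by minimizing
  $(1-\text{se})^2 + (1-\text{sp})^2$ — the closest-to-perfect-corner
  rule, *not* Youden's J; ties break toward the smaller threshold.
* **High-risk cut-off kappa**: eyes are classified at ≥ the per-method
  cut-off (0.03 mm³ on the cube-scan scale; its converted 0.083 mm³ on
  the raster scale) and summarized with Cohen's kappa and raw percent
  agreement.
* **Deming conversion**: errors-in-variables fit with λ = 1. λ is not
  documented for the published formulas, but λ = 1 is the only choice
  under which the two printed directions (0.473 and 2.112 ≈ 1/0.473)
  are near-inverses, and it makes A→B and B→A fits exact algebraic
  inverses. Before fitting, the optimal iAMD subset drops eyes where
  the cube value exceeds the raster value and eyes with per-eye mean
  above 0.2 mm³ (a mean of exactly 0.2 is retained); the data are then
  split 80/20 (train size `round(0.8 n)`, simple random, seeded —
  stratification is not documented and was not added).

## Running a study

```{r}
library(drusevol)

cfg <- study_config(
  sim = sim_cohort_config(
    n_per_stage = c(no_amd = 49, eamd = 25, iamd = 126),
    seed = 1
  )
)
bundle <- run_study(cfg)
bundle$agreement
write_report(bundle, "study_out", format = "csv")
```

`run_study()` is the one-command study: simulate, segment with the
per-device algorithm assignment (BM-offset for the raster profiles,
expected-RPE fit for the cube profile), quantify, and compare. Eyes
whose measurement fails are excluded with the reason recorded
(`bundle$exclusions`); included plus excluded always equals generated.
Everything is a pure function of the config, including its seed. The
module-level functions (`build_cohort()`, `measure_cohort()`,
`agreement_report()`, `roc_points()`, `deming_fit()`, …) are the
intended programmatic interface; `write_report()` and `write_cohort()`
serialize to plain CSV/JSON containers.

## What the simulation does and does not show

The generator reproduces the *structure* the analysis assumes:
stage-ordered right-skewed volumes, a multiplicative inter-device bias,
scan-density-dependent detection of medium drusen, and RPD lesions
captured inconsistently between devices. Under the default
configuration the simulated study reproduces the published ordering —
inter-scan ICC ≫ inter-device ICC in iAMD, eAMD sensitivity highest on
the dense raster scan and lowest on the biased cube scan, fitted
conversion slope close to the device bias — and the test suite asserts
those orderings over hundreds of simulated eyes.

It does **not** model B-scan intensities, speckle, optics, axial
curvature artifacts, segmentation-network failure modes, or real drusen
morphology; passing tests therefore show the *analysis pipeline* is
correct and the *mechanisms* are sufficient to produce the published
qualitative pattern, not that the generator is a faithful model of any
particular device. Magnitudes that depend on proprietary internals
(exact sensitivities, exact ICCs) are reproduced only qualitatively.

Problem sizes used by the checks (chosen as a balance of stability and
desk-scale runtime): detection asymmetry and inter-scan ICC over 200
eyes per stage; the RPD effect over 10 seeded replicates of 40 iAMD
eyes; the acceptance study at the published cohort composition
(49/25/126 eyes).

## Known limitations

* One eye per subject: the published cohort included both eyes for most
  subjects without intra-subject clustering adjustment; the generator
  sidesteps the issue rather than modeling it.
* The BM-offset estimator quantizes at the axial-pixel bin width, so
  per-eye floors can be off by up to about half a pixel; with the
  minimal-elevation mask this shifts volumes only through the drusen
  footprint area.
* Linear slow-axis interpolation is an assumption; the devices' native
  reconstruction schemes are proprietary.
* No confidence intervals on AUC or on Deming coefficients (none are
  published for comparison).
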