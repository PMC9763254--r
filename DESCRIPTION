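Package: drusevol
Title: Comparability of Automated Drusen Volume Measurements Across OCT
    Devices and Scan Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for comparing automated drusen
    volume measurements between optical coherence tomography (OCT) devices,
    segmentation algorithms and B-scan densities in early and intermediate
    age-related macular degeneration (AMD). Provides a synthetic cohort
    generator with analytic ground-truth drusen (spherical caps on a smooth
    Bruch's membrane), two drusen segmentation strategies (healthy-RPE floor
    from a fixed Bruch's membrane offset, and an iteratively refitted
    expected-RPE polynomial), en-face connected-component filtering of small
    elevations, fovea-centered circle volumetry with slow-axis interpolation,
    and the full method-agreement analysis: two-way intraclass correlation
    (consistency and agreement), Bland-Altman summaries, paired Wilcoxon and
    Jonckheere-Terpstra tests, ROC threshold selection by the
    closest-to-perfection criterion, Cohen's kappa against a high-risk
    cut-off, and Deming regression conversion formulae between devices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
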