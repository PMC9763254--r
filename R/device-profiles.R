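#' Define an OCT device / scan-pattern profile
#'
#' A device profile describes the sampling geometry of one scan pattern
#' (B-scan count and spacing along the slow axis, A-scan count and pitch along
#' the fast axis, axial pixel pitch) together with the measurement
#' idiosyncrasies the simulator imposes on it: additive Gaussian surface
#' noise, a systematic per-A-scan distortion of measured drusen height
#' (`bias_slope`, `bias_intercept_um`), and the probability that a reticular
#' pseudodrusen (RPD) lesion is reflected in the segmented RPE surface.
#'
#' @param name Label used in measurement tables (e.g. `"spectralis_dense"`).
#' @param n_bscans Number of B-scans (slow-axis rows); at least 2.
#' @param bscan_spacing_um Distance between consecutive B-scans in microns.
#' @param n_ascans Number of A-scans per B-scan (fast-axis columns).
#' @param ascan_pitch_um Distance between consecutive A-scans in microns.
#' @param axial_pitch_um Axial (depth) pixel pitch in microns; the
#'   small-elevation filter threshold is expressed in these pixels.
#' @param surface_noise_sd_um Standard deviation of the independent Gaussian
#'   noise added to each surface at each grid node, in microns.
#' @param bias_slope,bias_intercept_um Linear distortion applied to the true
#'   drusen height at nodes where drusen are present: the measured RPE is
#'   elevated by `bias_slope * height + bias_intercept_um` instead of
#'   `height`. A slope below 1 emulates a device that systematically
#'   under-reports drusen volume.
#' @param rpd_capture_prob Probability, per lesion and per scan, that an RPD
#'   lesion is captured by the segmented RPE surface.
#'
#' @return An object of class `device_profile`.
#' @examples
#' device_profile("toy", n_bscans = 25, bscan_spacing_um = 240,
#'                n_ascans = 64, ascan_pitch_um = 90)
#' @export
device_profile <- function(name,
                           n_bscans,
                           bscan_spacing_um,
                           n_ascans,
                           ascan_pitch_um,
                           axial_pitch_um = 3.9,
                           surface_noise_sd_um = 2,
                           bias_slope = 1,
                           bias_intercept_um = 0,
                           rpd_capture_prob = 0.7) {
  if (n_bscans < 2) {
    abort_drusevol("`n_bscans` must be at least 2.", "drusevol_bad_profile")
  }
  if (bscan_spacing_um <= 0 || ascan_pitch_um <= 0 || axial_pitch_um <= 0) {
    abort_drusevol("All pitches must be positive.", "drusevol_bad_profile")
  }
  if (rpd_capture_prob < 0 || rpd_capture_prob > 1) {
    abort_drusevol("`rpd_capture_prob` must lie in [0, 1].",
                   "drusevol_bad_profile")
  }
  structure(
    list(
      name = name,
      n_bscans = as.integer(n_bscans),
      bscan_spacing_um = bscan_spacing_um,
      n_ascans = as.integer(n_ascans),
      ascan_pitch_um = ascan_pitch_um,
      axial_pitch_um = axial_pitch_um,
      field_x_um = (n_ascans - 1) * ascan_pitch_um,
      field_y_um = (n_bscans - 1) * bscan_spacing_um,
      surface_noise_sd_um = surface_noise_sd_um,
      bias_slope = bias_slope,
      bias_intercept_um = bias_intercept_um,
      rpd_capture_prob = rpd_capture_prob
    ),
    class = "device_profile"
  )
}

#' Default scan-pattern profiles
#'
#' Three profiles mirroring the scan patterns commonly used for macular
#' drusen quantification: a dense 241-B-scan volume scan (30 um spacing,
#' 30 x 25 degree field), a sparse 25-B-scan scan (240 um spacing, 20 x 20
#' degree field) and a 200 x 200 macular cube over roughly 6 x 6 mm. Fields
#' are given directly in microns (about 290 um per degree). The cube profile
#' carries a drusen-height bias slope of 0.5 and a lower RPD capture
#' probability, emulating a device/algorithm pair that systematically
#' measures smaller drusen volumes and handles RPD lesions differently.
#'
#' @return Named list of [device_profile()] objects
#'   (`spectralis_dense`, `spectralis_sparse`, `cirrus`).
#' @export
default_device_profiles <- function() {
  list(
    spectralis_dense = device_profile(
      "spectralis_dense",
      n_bscans = 241, bscan_spacing_um = 30,
      n_ascans = 256, ascan_pitch_um = 34,
      rpd_capture_prob = 0.7
    ),
    spectralis_sparse = device_profile(
      "spectralis_sparse",
      n_bscans = 25, bscan_spacing_um = 240,
      n_ascans = 256, ascan_pitch_um = 22.7,
      rpd_capture_prob = 0.7
    ),
    cirrus = device_profile(
      "cirrus",
      n_bscans = 200, bscan_spacing_um = 30,
      n_ascans = 200, ascan_pitch_um = 30,
      bias_slope = 0.5,
      rpd_capture_prob = 0.3
    )
  )
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf(
    "<device_profile> %s: %d B-scans @ %g um, %d A-scans @ %g um (%g x %g um)\n",
    x$name, x$n_bscans, x$bscan_spacing_um, x$n_ascans, x$ascan_pitch_um,
    x$field_x_um, x$field_y_um
  ))
  cat(sprintf(
    "  axial pitch %g um, noise sd %g um, bias %g h + %g um, RPD capture %g\n",
    x$axial_pitch_um, x$surface_noise_sd_um, x$bias_slope,
    x$bias_intercept_um, x$rpd_capture_prob
  ))
  invisible(x)
}
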