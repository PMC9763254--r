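# Shared fixtures, built in code at test time.

# Flat surfaces: bm at `base`, rpe at base + gap, optional drusen heights
# added to the rpe.
flat_surfaces <- function(nr = 20, nc = 20, base = 100, gap = 35,
                          extra_rpe = 0, bscan_spacing_um = 30,
                          ascan_pitch_um = 30, axial_pitch_um = 3.9) {
  bm <- matrix(base, nr, nc)
  layer_surfaces(
    rpe_um = bm + gap + extra_rpe, bm_um = bm,
    bscan_spacing_um = bscan_spacing_um, ascan_pitch_um = ascan_pitch_um,
    axial_pitch_um = axial_pitch_um
  )
}

# A single-cap noiseless test eye with controllable geometry.
cap_eye <- function(base_diameter_um = 500, height_um = 60,
                    center_x_um = 0, center_y_um = 0, stage = "iamd") {
  structure(
    list(
      eye_id = "test", subject_id = "test", stage = stage,
      rpd_present = FALSE,
      fovea_x_um = 0, fovea_y_um = 0,
      field_x_um = 20000, field_y_um = 20000,
      bm_coef = c(c0 = 200, c1 = 0, c2 = 0, c3 = 0, c4 = 0, c5 = 0),
      rpe_offset_um = 35,
      bumps = tibble::tibble(
        center_x_um = center_x_um, center_y_um = center_y_um,
        base_diameter_um = base_diameter_um, height_um = height_um
      ),
      rpd = tibble::tibble(center_x_um = double(), center_y_um = double(),
                           diameter_um = double(), height_um = double())
    ),
    class = "gt_eye"
  )
}

# Noise-free measurement device with adjustable sampling.
quiet_device <- function(n_bscans, bscan_spacing_um, n_ascans,
                         ascan_pitch_um, bias_slope = 1, ...) {
  device_profile("quiet", n_bscans = n_bscans,
                 bscan_spacing_um = bscan_spacing_um,
                 n_ascans = n_ascans, ascan_pitch_um = ascan_pitch_um,
                 surface_noise_sd_um = 0, bias_slope = bias_slope, ...)
}

# Closed-form spherical cap volume in mm^3.
cap_volume_mm3 <- function(base_diameter_um, height_um) {
  a <- base_diameter_um / 2
  pi * height_um / 6 * (3 * a^2 + height_um^2) / 1e9
}

# Exhaustive 8-connected component labels by depth-first flood fill;
# independent of the package's igraph-based labeling.
flood_fill_labels <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (mask[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        stack <- list(c(i, j))
        while (length(stack)) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
          if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
          lab[p[1], p[2]] <- cur
          for (di in -1:1) for (dj in -1:1) {
            if (di || dj) stack[[length(stack) + 1L]] <- c(p[1] + di, p[2] + dj)
          }
        }
      }
    }
  }
  lab
}

# Paired tibble shorthand for the statistics tests.
paired <- function(a, b, stage = rep("iamd", length(a)),
                   rpd = rep(FALSE, length(a))) {
  tibble::tibble(
    eye_id = sprintf("e%03d", seq_along(a)),
    subject_id = sprintf("s%03d", seq_along(a)),
    stage = stage, rpd = rpd, value_a = a, value_b = b
  )
}
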