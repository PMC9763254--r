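test_that("build_eye enforces stage-specific Beckmann diameter classes", {
  cfg <- sim_cohort_config()
  set.seed(7)
  for (i in 1:50) {
    e <- build_eye("eamd", cfg)
    dmax <- max(e$bumps$base_diameter_um)
    expect_gt(dmax, 63)
    expect_lte(dmax, 125)
  }
  for (i in 1:50) {
    e <- build_eye("iamd", cfg)
    expect_gt(max(e$bumps$base_diameter_um), 125)
    expect_true(all(e$bumps$height_um <= e$bumps$base_diameter_um / 2))
  }
  for (i in 1:50) {
    e <- build_eye("no_amd", cfg)
    if (nrow(e$bumps)) expect_lte(max(e$bumps$base_diameter_um), 63)
  }
  expect_error(build_eye("late_amd", cfg), class = "drusevol_bad_stage")
})

test_that("a zero-bump distribution yields an empty bump list", {
  cfg <- sim_cohort_config()
  cfg$bumps$no_amd$count_lambda <- 0
  set.seed(1)
  e <- build_eye("no_amd", cfg)
  expect_identical(nrow(e$bumps), 0L)
  expect_equal(analytic_drusen_volume(e, 5), 0)
})

test_that("eye construction is a pure function of the RNG state", {
  cfg <- sim_cohort_config()
  set.seed(123)
  e1 <- build_eye("iamd", cfg)
  set.seed(123)
  e2 <- build_eye("iamd", cfg)
  expect_identical(e1, e2)
})

test_that("analytic volume matches the spherical-cap closed form", {
  e <- cap_eye(base_diameter_um = 500, height_um = 60)
  expect_equal(analytic_drusen_volume(e, 5), 0.006004, tolerance = 1e-4)
  expect_equal(analytic_drusen_volume(e, 5), cap_volume_mm3(500, 60),
               tolerance = 1e-9)
  # cap centered 5 mm from the fovea is outside a 5-mm diameter circle
  far <- cap_eye(center_x_um = 5000)
  expect_equal(analytic_drusen_volume(far, 5), 0)
})

test_that("straddling caps are clipped consistently with fine-grid integration", {
  # cap centered just inside the circle boundary
  e <- cap_eye(base_diameter_um = 400, height_um = 50, center_x_um = 2450)
  v <- analytic_drusen_volume(e, 5)
  expect_gt(v, 0)
  expect_lt(v, cap_volume_mm3(400, 50))
  # independent oracle: integrate the cap profile over a fine grid
  step <- 1
  xs <- seq(2250, 2650, by = step)
  ys <- seq(-200, 200, by = step)
  r <- sqrt(outer(ys^2, (xs - 2450)^2, "+"))
  a <- 200; h <- 50; R <- (a^2 + h^2) / (2 * h)
  z <- ifelse(r <= a, pmax(sqrt(pmax(R^2 - r^2, 0)) - (R - h), 0), 0)
  in_circ <- outer(ys^2, xs^2, "+") <= 2500^2
  expect_equal(v, sum(z * in_circ) * step^2 / 1e9, tolerance = 0.01)
})

test_that("analytic volume is invariant under rotation about the fovea", {
  set.seed(11)
  e <- build_eye("iamd", sim_cohort_config())
  v0 <- analytic_drusen_volume(e, 5)
  for (theta in c(pi / 7, pi / 2, 1.9 * pi)) {
    rot <- e
    x <- e$bumps$center_x_um
    y <- e$bumps$center_y_um
    rot$bumps$center_x_um <- cos(theta) * x - sin(theta) * y
    rot$bumps$center_y_um <- sin(theta) * x + cos(theta) * y
    expect_equal(analytic_drusen_volume(rot, 5), v0, tolerance = 1e-3)
  }
})

test_that("noise-free unbiased sampling reproduces cap heights exactly", {
  e <- cap_eye(base_diameter_um = 500, height_um = 60)
  dev <- quiet_device(41, 30, 41, 30)
  s <- simulate_scan(e, dev)
  nr <- dev$n_bscans; nc <- dev$n_ascans
  y <- (seq_len(nr) - (nr + 1) / 2) * 30
  x <- (seq_len(nc) - (nc + 1) / 2) * 30
  r <- sqrt(outer(y^2, x^2, "+"))
  a <- 250; h <- 60; R <- (a^2 + h^2) / (2 * h)
  expected <- ifelse(r <= a, pmax(sqrt(pmax(R^2 - r^2, 0)) - (R - h), 0), 0)
  expect_equal(s$rpe_um - s$bm_um - e$rpe_offset_um, expected,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a bias slope of one half roughly halves the measured volume", {
  e <- cap_eye(base_diameter_um = 500, height_um = 60)
  dev <- quiet_device(261, 20, 261, 20, bias_slope = 0.5)
  s <- simulate_scan(e, dev)
  m <- measure_eye(s, "bm_offset", target_row_spacing_um = 20,
                   min_elevation_um = 0)
  expect_equal(m$volume_5mm_mm3, 0.5 * cap_volume_mm3(500, 60),
               tolerance = 0.05)
})

test_that("uncaptured RPD lesions leave the surfaces untouched", {
  cfg <- sim_cohort_config()
  set.seed(5)
  eye_rpd <- build_eye("iamd", cfg, rpd_present = TRUE)
  eye_plain <- eye_rpd
  eye_plain$rpd_present <- FALSE
  eye_plain$rpd <- eye_plain$rpd[0, ]
  dev <- default_device_profiles()$spectralis_sparse
  dev$rpd_capture_prob <- 0
  set.seed(99)
  s1 <- simulate_scan(eye_rpd, dev)
  set.seed(99)
  s2 <- simulate_scan(eye_plain, dev)
  expect_identical(s1, s2)
})

test_that("scans reject devices wider than the eye's field", {
  e <- cap_eye()
  e$field_x_um <- 1000
  expect_error(simulate_scan(e, quiet_device(25, 240, 64, 90)),
               class = "drusevol_field_mismatch")
})

test_that("cohorts have exact stage counts and are seed-reproducible", {
  devs <- list(a = quiet_device(10, 240, 16, 120),
               b = quiet_device(6, 480, 16, 120))
  cfg <- sim_cohort_config(n_per_stage = c(no_amd = 3, eamd = 2, iamd = 4),
                           devices = devs, seed = 77)
  coh <- build_cohort(cfg)
  expect_identical(nrow(coh$manifest), 9L)
  expect_identical(sum(coh$manifest$stage == "iamd"), 4L)
  expect_identical(length(coh$scans), 9L)
  expect_identical(names(coh$scans[[1]]), c("a", "b"))
  coh2 <- build_cohort(cfg)
  expect_identical(coh, coh2)
  expect_error(build_cohort(sim_cohort_config(devices = list())),
               class = "drusevol_bad_config")
})

test_that("rpd_fraction_iamd = 1 flags every iAMD eye", {
  devs <- list(a = quiet_device(6, 480, 16, 120))
  cfg <- sim_cohort_config(n_per_stage = c(no_amd = 1, eamd = 1, iamd = 5),
                           rpd_fraction_iamd = 1, devices = devs, seed = 3)
  coh <- build_cohort(cfg)
  expect_true(all(coh$manifest$rpd_present[coh$manifest$stage == "iamd"]))
  expect_false(any(coh$manifest$rpd_present[coh$manifest$stage != "iamd"]))
})

test_that("mean truth volume rises across AMD stages by construction", {
  cfg <- sim_cohort_config()
  set.seed(2024)
  means <- vapply(c("no_amd", "eamd", "iamd"), function(st) {
    mean(vapply(1:70, function(i) {
      analytic_drusen_volume(build_eye(st, cfg), 5)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(means[["no_amd"]], means[["eamd"]])
  expect_lt(means[["eamd"]], means[["iamd"]])
})
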