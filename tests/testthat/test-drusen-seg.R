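test_that("RPE offset is the gap-histogram mode with low tie-break", {
  s <- flat_surfaces(gap = 35)
  expect_equal(estimate_rpe_offset(s), 35)

  # mode is robust to a minority of drusen-elevated nodes
  extra <- matrix(0, 20, 20)
  extra[1:4, 1:5] <- 50  # 5% of nodes
  s2 <- flat_surfaces(gap = 35, extra_rpe = extra)
  expect_equal(estimate_rpe_offset(s2), 35)

  # exact 50/50 bimodal gap: tie broken toward the smaller offset
  bm <- matrix(100, 10, 10)
  rpe <- bm + rep(c(30, 40), each = 50)
  s3 <- layer_surfaces(rpe, bm, 30, 30)
  expect_equal(estimate_rpe_offset(s3), 30)
})

test_that("inverted surfaces are flagged as implausible", {
  s <- flat_surfaces(gap = -10)
  expect_error(estimate_rpe_offset(s),
               class = "drusevol_implausible_segmentation")
})

test_that("floor_from_bm is the BM shifted by the offset", {
  s <- flat_surfaces(base = 100, gap = 35)
  expect_equal(floor_from_bm(s, 0), s$bm_um)
  f <- floor_from_bm(s, 35)
  expect_true(all(f == 135))
  expect_true(all(abs((f - s$bm_um) - 35) < 1e-12))
  expect_error(floor_from_bm(s, -1), class = "drusevol_bad_offset")
})

test_that("the expected-RPE fit reproduces a drusen-free polynomial RPE", {
  nc <- 64
  u <- seq(-1, 1, length.out = nc)
  row_shape <- 150 + 20 * u - 12 * u^2
  rpe <- t(matrix(row_shape, nc, 8))
  s <- layer_surfaces(rpe, rpe - 35, 240, 30)
  f <- floor_from_rpe_fit(s, degree = 3)
  expect_lt(max(abs(f - rpe)), 1)
})

test_that("the iterative fit excludes a druse and recovers its height", {
  nc <- 128
  u <- seq(-1, 1, length.out = nc)
  baseline <- 150 + 20 * u - 12 * u^2
  x_um <- (seq_len(nc) - (nc + 1) / 2) * 30
  cap <- ifelse(abs(x_um) <= 250, {
    a <- 250; h <- 60; R <- (a^2 + h^2) / (2 * h)
    pmax(sqrt(pmax(R^2 - x_um^2, 0)) - (R - h), 0)
  }, 0)
  rpe <- t(matrix(baseline + cap, nc, 6))
  s <- layer_surfaces(rpe, rpe * 0 + 100, 240, 30)
  f <- floor_from_rpe_fit(s, degree = 3, n_iter = 5, tol_um = 5)
  under <- abs(x_um) <= 250
  expect_lt(max(abs(f[1, ] - baseline)), 3)
  peak <- max(rpe[1, ] - f[1, ])
  expect_equal(peak, 60, tolerance = 0.05 * 60)

  # n_iter = 0 is the plain least-squares fit: it cuts through the cap
  f0 <- floor_from_rpe_fit(s, degree = 3, n_iter = 0)
  expect_gt(max(f0[1, under] - baseline[under]), 5)
})

test_that("degenerate fits are rejected", {
  s <- flat_surfaces(nr = 4, nc = 3)
  expect_error(floor_from_rpe_fit(s, degree = 3), class = "drusevol_bad_fit")
})

test_that("drusen heights clip at zero and track the floor", {
  s <- flat_surfaces(base = 100, gap = 40)  # rpe = 140
  m <- drusen_heights(s, matrix(135, 20, 20))
  expect_true(all(m$heights_um == 5))
  expect_false(m$filtered)
  m2 <- drusen_heights(s, matrix(145, 20, 20))
  expect_true(all(m2$heights_um == 0))
  m3 <- drusen_heights(s, s$rpe_um)
  expect_true(all(m3$heights_um == 0))
})

test_that("small-component filter drops sub-threshold peaks, keeps equals", {
  h <- matrix(0, 12, 12)
  h[2:3, 2:3] <- 4 * 3.9    # 15.6 um peak: below 5 px, filtered
  h[8:10, 8:10] <- 7 * 3.9  # 27.3 um peak: kept
  m <- drusen_map(h, 30, 30, axial_pitch_um = 3.9)
  f <- filter_small_components(m)
  expect_true(all(f$heights_um[2:3, 2:3] == 0))
  expect_true(all(f$heights_um[8:10, 8:10] == 7 * 3.9))
  expect_true(f$filtered)

  # a peak of exactly 5 px (19.5 um) is retained, not filtered
  h2 <- matrix(0, 5, 5)
  h2[2:3, 2:3] <- c(10, 10, 10, 19.5)
  m2 <- drusen_map(h2, 30, 30, axial_pitch_um = 3.9)
  f2 <- filter_small_components(m2)
  expect_equal(f2$heights_um, h2)

  # idempotence
  expect_equal(filter_small_components(f)$heights_um, f$heights_um)
})

test_that("filtering never increases total volume", {
  set.seed(41)
  for (i in 1:20) {
    h <- matrix(pmax(rnorm(100, 5, 10), 0), 10, 10)
    m <- drusen_map(h, 30, 30)
    f <- filter_small_components(m)
    expect_lte(sum(f$heights_um), sum(m$heights_um))
  }
})

test_that("component filtering matches exhaustive flood-fill enumeration", {
  set.seed(17)
  for (i in 1:40) {
    nr <- sample(2:4, 1)
    nc <- sample(2:5, 1)
    h <- matrix(sample(c(0, 10, 25), nr * nc, replace = TRUE,
                       prob = c(0.5, 0.25, 0.25)), nr, nc)
    m <- drusen_map(h, 30, 30, axial_pitch_um = 3.9)
    f <- filter_small_components(m, min_height_px = 5)
    lab <- flood_fill_labels(h > 0)
    expected <- h
    for (k in seq_len(max(lab))) {
      if (max(h[lab == k]) < 19.5) expected[lab == k] <- 0
    }
    expect_identical(f$heights_um, expected)
  }
})

test_that("both floor algorithms agree on noise-free synthetic scans", {
  set.seed(31)
  eye <- build_eye("iamd", sim_cohort_config())
  dev <- quiet_device(101, 50, 175, 50)
  s <- simulate_scan(eye, dev)
  f_bm <- floor_from_bm(s)
  f_fit <- floor_from_rpe_fit(s)
  drus <- s$rpe_um - s$bm_um - eye$rpe_offset_um
  outside <- drus < 1e-9
  expect_lt(max(abs(f_bm[outside] - f_fit[outside])), 3)
  v_bm <- volume_in_circle(drusen_heights(s, f_bm), 5)
  v_fit <- volume_in_circle(drusen_heights(s, f_fit), 5)
  expect_equal(v_bm, v_fit, tolerance = 0.05)
  expect_equal(v_bm, analytic_drusen_volume(eye, 5), tolerance = 0.05)
})
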