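#' Estimate the physiologic BM-to-RPE offset of an eye
#'
#' The healthy RPE runs at a roughly fixed distance above Bruch's membrane;
#' that distance varies between individuals, so it is estimated per eye as
#' the mode of the histogram of `rpe - bm` across all grid nodes, using a
#' bin width of one axial pixel. Drusen lift the RPE at a minority of nodes
#' and do not move the mode. Ties between modal bins are broken toward the
#' smaller offset; the returned value is the median gap within the modal
#' bin.
#'
#' @param s A [layer_surfaces()] object.
#' @return Offset in microns.
#' @export
estimate_rpe_offset <- function(s) {
  gap <- as.vector(s$rpe_um - s$bm_um)
  if (!length(gap)) {
    abort_drusevol("Surfaces are empty.", "drusevol_bad_surfaces")
  }
  if (mean(gap < 0) > 0.5) {
    abort_drusevol(
      "RPE lies below BM over more than half the grid; segmentation implausible.",
      "drusevol_implausible_segmentation"
    )
  }
  width <- s$axial_pitch_um
  bin <- floor((gap - min(gap)) / width)
  counts <- table(bin)
  top <- as.integer(names(counts)[counts == max(counts)])
  modal <- min(top)  # tie-break toward the smaller offset
  stats::median(gap[bin == modal])
}

#' Healthy-RPE floor from the BM surface
#'
#' The BM-offset algorithm: the drusen-free ("healthy") RPE is the measured
#' BM elevated by the eye's physiologic offset.
#'
#' @param s A [layer_surfaces()] object.
#' @param offset_um Non-negative BM-to-RPE distance, typically from
#'   [estimate_rpe_offset()].
#' @return Floor elevation matrix (microns), same shape as the surfaces.
#' @export
floor_from_bm <- function(s, offset_um = estimate_rpe_offset(s)) {
  if (offset_um < 0) {
    abort_drusevol("`offset_um` must be non-negative.", "drusevol_bad_offset")
  }
  s$bm_um + offset_um
}

#' Healthy-RPE floor by iterative polynomial fitting of the RPE
#'
#' The expected-RPE algorithm: per B-scan, a polynomial of the given degree
#' is fitted to the segmented RPE, and the fit is iteratively restricted to
#' drusen-free support - nodes where the RPE lies within `tol_um` above the
#' current fit. Nodes under drusen sit far above the fit and are excluded
#' after the first iterations, so the final fit tracks the drusen-free RPE
#' shape. With `n_iter = 0` the plain least-squares fit is returned.
#'
#' @param s A [layer_surfaces()] object.
#' @param degree Polynomial degree per B-scan (default 3).
#' @param n_iter Number of support-refinement iterations (default 5).
#' @param tol_um Support tolerance above the fit, microns (default 5).
#' @return Floor elevation matrix (microns).
#' @export
floor_from_rpe_fit <- function(s, degree = 3, n_iter = 5, tol_um = 5) {
  nc <- ncol(s$rpe_um)
  if (nc < degree + 1) {
    abort_drusevol("Each B-scan needs at least degree + 1 A-scans.",
                   "drusevol_bad_fit")
  }
  u <- seq(-1, 1, length.out = nc)
  X <- outer(u, 0:degree, "^")
  out <- matrix(0, nrow(s$rpe_um), nc)
  for (i in seq_len(nrow(s$rpe_um))) {
    y <- s$rpe_um[i, ]
    keep <- rep(TRUE, nc)
    fit <- drop(X %*% poly_coef(X, y, keep))
    if (n_iter > 0) {
      for (it in seq_len(n_iter)) {
        keep <- y <= fit + tol_um
        if (sum(keep) < degree + 1) {
          abort_drusevol("Degenerate fit: too few support nodes.",
                         "drusevol_bad_fit")
        }
        fit <- drop(X %*% poly_coef(X, y, keep))
      }
    }
    out[i, ] <- fit
  }
  out
}

poly_coef <- function(X, y, keep) {
  f <- lm.fit(X[keep, , drop = FALSE], y[keep])
  if (any(is.na(f$coefficients))) {
    abort_drusevol("Degenerate fit: singular design.", "drusevol_bad_fit")
  }
  f$coefficients
}

#' Drusen heights above a healthy-RPE floor
#'
#' Drusen are the material between the segmented RPE and the healthy RPE
#' floor: `heights = max(rpe - floor, 0)` elementwise.
#'
#' @param s A [layer_surfaces()] object.
#' @param floor_um Floor matrix from [floor_from_bm()] or
#'   [floor_from_rpe_fit()].
#' @return A `drusen_map` (unfiltered).
#' @export
drusen_heights <- function(s, floor_um) {
  if (!identical(dim(floor_um), dim(s$rpe_um))) {
    abort_drusevol("Floor shape must match the surfaces.",
                   "drusevol_bad_surfaces")
  }
  drusen_map(
    heights_um = pmax(s$rpe_um - floor_um, 0),
    bscan_spacing_um = s$bscan_spacing_um,
    ascan_pitch_um = s$ascan_pitch_um,
    axial_pitch_um = s$axial_pitch_um,
    fovea_row = s$fovea_row, fovea_col = s$fovea_col,
    filtered = FALSE
  )
}

#' Construct an en-face drusen height map
#'
#' @param heights_um Non-negative en-face height matrix (rows = B-scans).
#' @param bscan_spacing_um,ascan_pitch_um,axial_pitch_um Grid metadata.
#' @param fovea_row,fovea_col Fovea grid position.
#' @param filtered Has the small-component filter been applied?
#' @return Object of class `drusen_map`.
#' @export
drusen_map <- function(heights_um, bscan_spacing_um, ascan_pitch_um,
                       axial_pitch_um = 3.9,
                       fovea_row = (nrow(heights_um) + 1) / 2,
                       fovea_col = (ncol(heights_um) + 1) / 2,
                       filtered = FALSE) {
  if (any(heights_um < 0)) {
    abort_drusevol("Drusen heights must be non-negative.", "drusevol_bad_map")
  }
  structure(
    list(heights_um = heights_um,
         bscan_spacing_um = bscan_spacing_um,
         ascan_pitch_um = ascan_pitch_um,
         axial_pitch_um = axial_pitch_um,
         fovea_row = fovea_row, fovea_col = fovea_col,
         filtered = filtered),
    class = "drusen_map"
  )
}

#' @export
print.drusen_map <- function(x, ...) {
  cat(sprintf(
    "<drusen_map> %d x %d (%g x %g um pitch), %s, max height %.1f um\n",
    nrow(x$heights_um), ncol(x$heights_um), x$bscan_spacing_um,
    x$ascan_pitch_um, if (x$filtered) "filtered" else "unfiltered",
    max(x$heights_um)
  ))
  invisible(x)
}

# 8-connected labeling of the positive-height en-face mask via igraph
# components on a vectorized neighbour edge list. Returns an integer matrix,
# 0 = background.
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, nr, nc)
  if (!length(idx)) return(out)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- vector("list", 4)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(shifts)) {
    r2 <- r + shifts[[k]][1]
    c2 <- cc + shifts[[k]][2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    lin <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- mask[lin]
    edges[[k]] <- rbind(idx[ok][ok2], lin[ok2])
  }
  e <- do.call(cbind, edges)
  member <- if (is.null(e) || !ncol(e)) {
    seq_along(idx)
  } else {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    g <- igraph::add_edges(g, match(as.vector(e), idx))
    igraph::components(g)$membership
  }
  out[idx] <- as.integer(member)
  out
}

#' Filter small false-positive RPE elevations
#'
#' Labels 8-connected components of the positive-height en-face mask and
#' zeroes every component whose maximum height is strictly below
#' `min_height_px` axial pixels (with the default 3.9 um axial pitch,
#' 5 px = 19.5 um). Components peaking exactly at the threshold are kept.
#' Idempotent.
#'
#' @param m A `drusen_map`.
#' @param min_height_px Threshold in axial pixels (default 5).
#' @return The filtered `drusen_map` (`filtered = TRUE`).
#' @export
filter_small_components <- function(m, min_height_px = 5) {
  if (min_height_px < 0) {
    abort_drusevol("`min_height_px` must be non-negative.",
                   "drusevol_bad_filter")
  }
  thr <- filter_threshold_um(min_height_px, m$axial_pitch_um)
  h <- m$heights_um
  lab <- label_components(h > 0)
  if (max(lab) > 0) {
    peak <- vapply(split(h[lab > 0], lab[lab > 0]), max, numeric(1))
    drop_ids <- as.integer(names(peak)[peak < thr])
    h[lab %in% drop_ids] <- 0
  }
  m$heights_um <- h
  m$filtered <- TRUE
  m
}

#' Small-elevation filter threshold in microns
#'
#' @param min_height_px Threshold in axial pixels.
#' @param axial_pitch_um Axial pixel pitch in microns.
#' @return Threshold in microns (e.g. 5 px at 3.9 um = 19.5 um).
#' @export
filter_threshold_um <- function(min_height_px = 5, axial_pitch_um = 3.9) {
  min_height_px * axial_pitch_um
}
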