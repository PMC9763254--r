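#' Read and write layer-surface containers
#'
#' The on-disk container for one scanned eye is plain text: two headerless
#' CSV grids (`<prefix>_rpe.csv`, `<prefix>_bm.csv`, values in microns,
#' rows = B-scans) plus a JSON sidecar (`<prefix>.json`) carrying the grid
#' metadata. [read_surfaces()] accepts any conforming files.
#'
#' @param s A [layer_surfaces()] object.
#' @param prefix File path prefix (no extension).
#' @return `write_surfaces()` returns the prefix invisibly;
#'   `read_surfaces()` returns a `layer_surfaces`.
#' @export
write_surfaces <- function(s, prefix) {
  write_grid(s$rpe_um, paste0(prefix, "_rpe.csv"))
  write_grid(s$bm_um, paste0(prefix, "_bm.csv"))
  jsonlite::write_json(
    list(bscan_spacing_um = s$bscan_spacing_um,
         ascan_pitch_um = s$ascan_pitch_um,
         axial_pitch_um = s$axial_pitch_um,
         fovea_row = s$fovea_row, fovea_col = s$fovea_col),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_surfaces
#' @export
read_surfaces <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  layer_surfaces(
    rpe_um = read_grid(paste0(prefix, "_rpe.csv")),
    bm_um = read_grid(paste0(prefix, "_bm.csv")),
    bscan_spacing_um = meta$bscan_spacing_um,
    ascan_pitch_um = meta$ascan_pitch_um,
    axial_pitch_um = meta$axial_pitch_um,
    fovea_row = meta$fovea_row, fovea_col = meta$fovea_col
  )
}

#' Read and write en-face drusen maps
#'
#' Single headerless CSV grid of heights (microns) plus a JSON metadata
#' sidecar, mirroring the layer-surface container.
#'
#' @param m A `drusen_map`.
#' @param prefix File path prefix (no extension).
#' @return `write_drusen_map()` returns the prefix invisibly;
#'   `read_drusen_map()` returns a `drusen_map`.
#' @export
write_drusen_map <- function(m, prefix) {
  write_grid(m$heights_um, paste0(prefix, "_drusen.csv"))
  jsonlite::write_json(
    list(bscan_spacing_um = m$bscan_spacing_um,
         ascan_pitch_um = m$ascan_pitch_um,
         axial_pitch_um = m$axial_pitch_um,
         fovea_row = m$fovea_row, fovea_col = m$fovea_col,
         filtered = m$filtered),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_drusen_map
#' @export
read_drusen_map <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  drusen_map(
    heights_um = read_grid(paste0(prefix, "_drusen.csv")),
    bscan_spacing_um = meta$bscan_spacing_um,
    ascan_pitch_um = meta$ascan_pitch_um,
    axial_pitch_um = meta$axial_pitch_um,
    fovea_row = meta$fovea_row, fovea_col = meta$fovea_col,
    filtered = meta$filtered
  )
}

write_grid <- function(mat, path) {
  utils::write.table(mat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

read_grid <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Serialize a cohort to a directory
#'
#' Writes `manifest.csv`, `config.json` (seed and distribution parameters)
#' and, per eye and device, a layer-surface container under
#' `surfaces/<eye_id>_<device>`.
#'
#' @param cohort A [build_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "surfaces"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_csv(cohort$manifest, file.path(dir, "manifest.csv"))
  cfg <- cohort$config
  cfg$devices <- lapply(cfg$devices, unclass)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (eye_id in names(cohort$scans)) {
    for (dev in names(cohort$scans[[eye_id]])) {
      write_surfaces(cohort$scans[[eye_id]][[dev]],
                     file.path(dir, "surfaces", paste0(eye_id, "_", dev)))
    }
  }
  invisible(dir)
}
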