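#' Bland-Altman plot of paired measurements
#'
#' Per-eye mean of the two methods against their difference, with the mean
#' difference and 1.96-sd limits of agreement as horizontal lines, colored
#' by AMD stage when available.
#'
#' @param p Paired tibble from [pair_measures()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(p) {
  ba <- bland_altman(p)
  df <- dplyr::mutate(p, avg = (.data$value_a + .data$value_b) / 2,
                      diff = .data$value_a - .data$value_b)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff))
  gg <- if ("stage" %in% names(df)) {
    gg + ggplot2::geom_point(ggplot2::aes(color = .data$stage), alpha = 0.7)
  } else {
    gg + ggplot2::geom_point(alpha = 0.7)
  }
  gg +
    ggplot2::geom_hline(yintercept = ba$mean_diff, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods (mm^3)",
                  y = "Difference a - b (mm^3)")
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", attr(object, "auc")))
}

#' En-face drusen height map image
#'
#' @param m A `drusen_map`.
#' @return A ggplot raster of heights (microns) in en-face coordinates.
#' @export
plot_drusen_map <- function(m) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(m$heights_um)), col = seq_len(ncol(m$heights_um))
  )
  df$height <- as.vector(t(m$heights_um))
  df$x_um <- (df$col - m$fovea_col) * m$ascan_pitch_um
  df$y_um <- (df$row - m$fovea_row) * m$bscan_spacing_um
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Fast axis (um)", y = "Slow axis (um)",
                  fill = "Height (um)")
}
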