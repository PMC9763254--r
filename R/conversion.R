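#' Deming regression between two measurement methods
#'
#' Errors-in-variables straight-line fit treating both methods as noisy,
#' with error-variance ratio `lambda` (default 1, orthogonal regression;
#' with `lambda = 1` the x-on-y and y-on-x fits are exact inverses).
#' Closed-form solution:
#' \deqn{slope = \frac{s_{yy} - \lambda s_{xx} +
#'   \sqrt{(s_{yy} - \lambda s_{xx})^2 + 4 \lambda s_{xy}^2}}{2 s_{xy}},
#'   \quad intercept = \bar y - slope\,\bar x.}
#'
#' @param x,y Numeric vectors (source and target method), `n >= 3`.
#' @param lambda Ratio of error variances (error in y over error in x);
#'   must be positive.
#' @return Object of class `deming_fit`: `slope`, `intercept`, `lambda`,
#'   `n`.
#' @export
deming_fit <- function(x, y, lambda = 1) {
  if (length(x) != length(y) || length(x) < 3) {
    abort_drusevol("Need at least 3 complete pairs.", "drusevol_bad_deming")
  }
  if (lambda <= 0) {
    abort_drusevol("`lambda` must be positive.", "drusevol_bad_deming")
  }
  sxx <- var(x)
  syy <- var(y)
  sxy <- cov(x, y)
  if (abs(sxy) < .Machine$double.eps * max(1, sxx, syy)) {
    abort_drusevol("Zero covariance: no identifiable line.",
                   "drusevol_bad_deming")
  }
  slope <- (syy - lambda * sxx +
              sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  structure(
    list(slope = slope, intercept = mean(y) - slope * mean(x),
         lambda = lambda, n = length(x)),
    class = "deming_fit"
  )
}

#' Construct a Deming fit from known coefficients
#'
#' @param slope,intercept Line coefficients (slope must be nonzero).
#' @param lambda Error-variance ratio recorded on the fit.
#' @param n Number of observations behind the coefficients (may be `NA`).
#' @return A `deming_fit`.
#' @export
deming_coefficients <- function(slope, intercept, lambda = 1, n = NA_integer_) {
  if (!is.finite(slope) || slope == 0) {
    abort_drusevol("Slope must be finite and nonzero.", "drusevol_bad_deming")
  }
  structure(list(slope = slope, intercept = intercept, lambda = lambda, n = n),
            class = "deming_fit")
}

#' Published inter-device conversion coefficients
#'
#' The conversion formulae reported for a multi-center iAMD cohort between
#' the cube-scan device algorithm ("cirrus") and the dense raster-scan
#' algorithm ("spectralis"):
#' cirrus = spectralis x 0.473 - 0.0091 mm^3 and
#' spectralis = cirrus x 2.112 + 0.0193 mm^3. Shipped as named constants
#' for worked examples and cut-off conversion; freshly fitted values from
#' [deming_fit()] are a different thing.
#'
#' @return Named list of two `deming_fit` objects:
#'   `spectralis_to_cirrus`, `cirrus_to_spectralis`.
#' @export
reference_conversion <- function() {
  list(
    spectralis_to_cirrus = deming_coefficients(0.473, -0.0091),
    cirrus_to_spectralis = deming_coefficients(2.112, 0.0193)
  )
}

#' Apply or invert a conversion line
#'
#' `apply_fit()` converts source-method values with `slope * value +
#' intercept`; `invert_fit()` returns the inverse line (`1/slope`,
#' `-intercept/slope`), so `apply_fit(invert_fit(f), apply_fit(f, v)) = v`.
#'
#' @param fit A `deming_fit`.
#' @param value Numeric vector to convert.
#' @return Converted values; or the inverted `deming_fit`.
#' @export
apply_fit <- function(fit, value) {
  fit$slope * value + fit$intercept
}

#' @rdname apply_fit
#' @export
invert_fit <- function(fit) {
  if (fit$slope == 0) {
    abort_drusevol("Cannot invert a zero-slope fit.", "drusevol_bad_deming")
  }
  deming_coefficients(1 / fit$slope, -fit$intercept / fit$slope,
                      lambda = 1 / fit$lambda, n = fit$n)
}

#' Select the optimal subset for conversion fitting
#'
#' Restricts paired measurements to the region where the inter-device
#' relation is linear: drops eyes where the cube-scan ("cirrus-like")
#' value exceeds the raster-scan ("spectralis-like") value, and eyes whose
#' per-eye mean of the two values exceeds `mean_cap` (strictly; a mean of
#' exactly `mean_cap` is retained). Row order is preserved.
#'
#' @param p Paired tibble with `value_a`, `value_b`.
#' @param spectralis_col,cirrus_col Which column plays which role
#'   (defaults: `value_a` is spectralis-like, `value_b` cirrus-like).
#' @param mean_cap Upper cap on the per-eye mean value, mm^3 (default 0.2).
#' @return The filtered tibble; errors with a named status if empty.
#' @export
select_optimal_subset <- function(p, spectralis_col = "value_a",
                                  cirrus_col = "value_b", mean_cap = 0.2) {
  check_paired(p, min_n = 1)
  s <- p[[spectralis_col]]
  cc <- p[[cirrus_col]]
  keep <- !(cc > s) & ((s + cc) / 2 <= mean_cap)
  out <- p[keep, ]
  if (!nrow(out)) {
    abort_drusevol("Optimal subset is empty.", "drusevol_empty_subset")
  }
  out
}

#' Seeded train/test split of paired measurements
#'
#' Random, disjoint, exhaustive partition with `round(n * train_frac)`
#' training rows. Reproducible under the given seed; the caller's RNG
#' state is untouched.
#'
#' @param p Paired tibble (`n >= 5`).
#' @param train_frac Training fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
train_test_split <- function(p, train_frac = 0.8, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) {
    abort_drusevol("`train_frac` must lie strictly in (0, 1).",
                   "drusevol_bad_split")
  }
  n <- nrow(p)
  if (n < 5) {
    abort_drusevol("Need at least 5 rows to split.", "drusevol_bad_split")
  }
  n_train <- round(n * train_frac)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = p[sort(idx), ], test = p[setdiff(seq_len(n), idx), ])
}

#' Evaluate a conversion line on held-out pairs
#'
#' Converts the source-method values of the test set through the fit and
#' compares with the observed target-method values.
#'
#' @param fit A `deming_fit` mapping source to target.
#' @param test Paired tibble; non-empty.
#' @param from,to Source and target columns (defaults `value_b` ->
#'   `value_a`).
#' @param direction Label recorded in the output.
#' @return One-row tibble: `direction`, `n_test`, `mean_error`, `rmse`
#'   (converted minus observed, mm^3).
#' @export
evaluate_conversion <- function(fit, test, from = "value_b", to = "value_a",
                                direction = paste(from, "->", to)) {
  if (!nrow(test)) {
    abort_drusevol("Empty test set.", "drusevol_bad_split")
  }
  err <- apply_fit(fit, test[[from]]) - test[[to]]
  tibble(direction = direction, n_test = length(err),
         mean_error = mean(err), rmse = sqrt(mean(err^2)))
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf(
    "<deming_fit> y = %.4f x + %.5f (lambda = %g, n = %s)\n",
    x$slope, x$intercept, x$lambda, format(x$n)
  ))
  invisible(x)
}
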