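#' Tidy a Deming fit
#'
#' @param x A `deming_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`term`, `estimate`).
#' @export
tidy.deming_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' One-row summary of a Deming fit
#'
#' @param x A `deming_fit`.
#' @param ... Unused.
#' @return Tibble: `slope`, `intercept`, `lambda`, `n`.
#' @export
glance.deming_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, lambda = x$lambda,
         n = x$n)
}

#' Tidy an ROC curve
#'
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @return Tibble of `threshold`, `sensitivity`, `specificity`.
#' @export
tidy.roc_curve <- function(x, ...) {
  tibble(threshold = x$threshold, sensitivity = x$sensitivity,
         specificity = x$specificity)
}

#' One-row summary of an ROC curve
#'
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @return Tibble: `auc`, `n_case`, `n_control`.
#' @export
glance.roc_curve <- function(x, ...) {
  tibble(auc = attr(x, "auc"), n_case = attr(x, "n_case"),
         n_control = attr(x, "n_control"))
}
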