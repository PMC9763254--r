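#' ROC curve for drusen-based case/control discrimination
#'
#' Builds the ROC curve of a volume measurement for discriminating cases
#' (eyes with AMD) from controls. Candidate thresholds are the unique
#' observed values plus `Inf`; an eye is classified positive iff its value
#' is at or above the threshold. The AUC is computed from the rank
#' (Mann-Whitney) statistic with ties counted one half.
#'
#' @param values Numeric measurement vector.
#' @param labels Logical (or 0/1) vector; `TRUE` = case.
#' @return A `roc_curve`: tibble with `threshold`, `sensitivity`,
#'   `specificity`, carrying `auc`, `n_case`, `n_control` attributes.
#' @export
roc_points <- function(values, labels) {
  labels <- as.logical(labels)
  if (length(values) != length(labels) || anyNA(values) || anyNA(labels)) {
    abort_drusevol("`values` and `labels` must be complete and equal-length.",
                   "drusevol_bad_roc")
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    abort_drusevol("Need at least one case and one control.",
                   "drusevol_bad_roc")
  }
  thr <- c(sort(unique(values)), Inf)
  sens <- vapply(thr, function(t) mean(values[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(values[!labels] < t), numeric(1))
  r <- rank(values)  # midranks for ties
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(
    tibble(threshold = thr, sensitivity = sens, specificity = spec),
    auc = auc, n_case = n1, n_control = n0,
    class = c("roc_curve", class(tibble()))
  )
}

#' Optimal ROC threshold by the closest-to-perfection criterion
#'
#' Selects the threshold minimizing
#' `(1 - sensitivity)^2 + (1 - specificity)^2`, i.e. the operating point
#' closest to the perfect corner of ROC space (not Youden's J). Ties are
#' broken toward the smaller threshold.
#'
#' @param curve A `roc_curve` from [roc_points()].
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `criterion`.
#' @export
optimal_threshold <- function(curve) {
  if (!nrow(curve)) {
    abort_drusevol("Empty ROC curve.", "drusevol_bad_roc")
  }
  crit <- (1 - curve$sensitivity)^2 + (1 - curve$specificity)^2
  i <- which(crit <= min(crit) + 1e-12)
  i <- i[which.min(curve$threshold[i])]
  tibble(threshold = curve$threshold[i],
         sensitivity = curve$sensitivity[i],
         specificity = curve$specificity[i],
         criterion = crit[i])
}

#' Sensitivity by AMD stage and overall specificity at a threshold
#'
#' Specificity is computed on the no-AMD eyes; sensitivity overall (all
#' AMD eyes) and within each AMD stage, classifying positive at or above
#' the threshold. Empty strata are reported with `NA`.
#'
#' @param values Numeric measurement vector.
#' @param stages Character vector over `c("no_amd", "eamd", "iamd")`.
#' @param threshold Classification threshold.
#' @return Tibble: `stratum`, `metric`, `n`, `estimate` (proportion in
#'   `[0, 1]`).
#' @export
sens_spec_by_stage <- function(values, stages, threshold) {
  if (!all(stages %in% amd_stages())) {
    abort_drusevol("Stages must be drawn from no_amd/eamd/iamd.",
                   "drusevol_bad_stage")
  }
  pos <- values >= threshold
  strata <- list(
    no_amd = list(metric = "specificity", sel = stages == "no_amd"),
    all_amd = list(metric = "sensitivity", sel = stages != "no_amd"),
    eamd = list(metric = "sensitivity", sel = stages == "eamd"),
    iamd = list(metric = "sensitivity", sel = stages == "iamd")
  )
  dplyr::bind_rows(lapply(names(strata), function(nm) {
    sel <- strata[[nm]]$sel
    est <- if (!any(sel)) NA_real_ else if (strata[[nm]]$metric == "specificity") {
      mean(!pos[sel])
    } else {
      mean(pos[sel])
    }
    tibble(stratum = nm, metric = strata[[nm]]$metric, n = sum(sel),
           estimate = est)
  }))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f (%d cases, %d controls)\n",
              attr(x, "auc"), attr(x, "n_case"), attr(x, "n_control")))
  NextMethod()
}
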