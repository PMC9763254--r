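#' Pair two methods' measurements eye by eye
#'
#' Reshapes a long measurements table (one row per eye x method) into the
#' paired format the agreement statistics consume. Orientation matters for
#' signed summaries: differences are computed as `value_a - value_b`, so put
#' the denser / reference method first.
#'
#' @param measurements Tibble with columns `eye_id`, `subject_id`, `stage`,
#'   `rpd`, `method` and the value column.
#' @param method_a,method_b Method labels to pair.
#' @param value Name of the value column (default `"volume_5mm_mm3"`).
#' @return Tibble: `eye_id`, `subject_id`, `stage`, `rpd`, `value_a`,
#'   `value_b`; only eyes measured by both methods are kept.
#' @export
pair_measures <- function(measurements, method_a, method_b,
                          value = "volume_5mm_mm3") {
  a <- measurements[measurements$method == method_a, ]
  b <- measurements[measurements$method == method_b, ]
  out <- dplyr::inner_join(
    dplyr::select(a, "eye_id", "subject_id", "stage", "rpd",
                  value_a = dplyr::all_of(value)),
    dplyr::select(b, "eye_id", value_b = dplyr::all_of(value)),
    by = "eye_id"
  )
  attr(out, "methods") <- c(a = method_a, b = method_b)
  out
}

check_paired <- function(p, min_n = 1) {
  if (!all(c("value_a", "value_b") %in% names(p))) {
    abort_drusevol("Expected columns `value_a` and `value_b`.",
                   "drusevol_bad_paired")
  }
  if (anyNA(p$value_a) || anyNA(p$value_b)) {
    abort_drusevol("Paired measures must not contain missing values.",
                   "drusevol_bad_paired")
  }
  if (nrow(p) < min_n) {
    abort_drusevol(sprintf("At least %d paired eyes are required.", min_n),
                   "drusevol_bad_paired")
  }
  invisible(p)
}

# Two-way ANOVA mean squares for an n x k matrix (subjects x raters).
two_way_ms <- function(M) {
  n <- nrow(M)
  k <- ncol(M)
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((M - grand)^2)
  sse <- sst - ssr - ssc
  list(
    msr = ssr / (n - 1),
    msc = ssc / (k - 1),
    mse = sse / ((n - 1) * (k - 1)),
    n = n, k = k
  )
}

#' Two-way intraclass correlation (single measurement)
#'
#' Two-way random-effects, single-measurement ICC in its consistency and
#' agreement flavours. Consistency compares measures without penalizing a
#' systematic between-method shift (`x = y + e`); agreement penalizes it
#' (`x = y`), so a constant inter-device offset leaves consistency unchanged
#' but lowers agreement. From the two-way mean squares (subjects MSR,
#' methods MSC, residual MSE; k methods, n eyes):
#' consistency `(MSR - MSE) / (MSR + (k-1) MSE)`; agreement adds
#' `(k/n) (MSC - MSE)` to the denominator (negative method-variance
#' component truncated at zero). Confidence intervals follow the standard
#' F-based constructions (exact F for consistency, Satterthwaite
#' approximation for agreement).
#'
#' @param p Paired tibble from [pair_measures()] (columns `value_a`,
#'   `value_b`).
#' @param type `"consistency"` or `"agreement"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return One-row tibble: `type`, `estimate`, `conf_low`, `conf_high`,
#'   `n`, `status` (`"ok"`, or `"undefined_between_variance"` when the
#'   between-eye variance is zero and the ICC is not interpretable).
#' @export
icc_two_way <- function(p, type = c("consistency", "agreement"),
                        conf_level = 0.95) {
  type <- match.arg(type)
  check_paired(p, min_n = 3)
  M <- cbind(p$value_a, p$value_b)
  ms <- two_way_ms(M)
  n <- ms$n
  k <- ms$k
  if (ms$msr <= .Machine$double.eps * max(1, mean(M)^2)) {
    return(tibble(type = type, estimate = NA_real_, conf_low = NA_real_,
                  conf_high = NA_real_, n = n,
                  status = "undefined_between_variance"))
  }
  alpha <- 1 - conf_level
  if (type == "consistency") {
    est <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    if (ms$mse > 0) {
      fobs <- ms$msr / ms$mse
      fl <- fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    } else {
      lo <- hi <- 1
    }
  } else {
    pen <- (k / n) * max(ms$msc - ms$mse, 0)
    est <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse + pen)
    if (ms$mse > 0 || ms$msc > 0) {
      a <- (k * est) / (n * (1 - est))
      b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
      v <- (a * ms$msc + b * ms$mse)^2 /
        ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
      fl <- qf(1 - alpha / 2, n - 1, v)
      fu <- qf(1 - alpha / 2, v, n - 1)
      lo <- n * (ms$msr - fl * ms$mse) /
        (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
      hi <- n * (fu * ms$msr - ms$mse) /
        (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
    } else {
      lo <- hi <- 1
    }
  }
  tibble(type = type, estimate = est,
         conf_low = if (is.finite(lo)) lo else NA_real_,
         conf_high = if (is.finite(hi)) hi else NA_real_,
         n = n, status = "ok")
}

#' Bland-Altman summary of paired measurements
#'
#' Differences are oriented `value_a - value_b`. The limits of agreement
#' are `mean_diff +/- 1.96 sd_diff`. The standardized mean difference
#' divides the mean difference by the mean (over eyes) of the two methods'
#' per-eye averages, expressing the systematic shift as a fraction of the
#' measured magnitude.
#'
#' @param p Paired tibble with `value_a`, `value_b` (at least 2 eyes).
#' @return One-row tibble: `n`, `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `mean_of_averages`, `std_mean_diff`, `status`
#'   (`"degenerate_zero_mean"` when all per-eye averages are zero and the
#'   standardized difference is undefined).
#' @export
bland_altman <- function(p) {
  check_paired(p, min_n = 2)
  d <- p$value_a - p$value_b
  avg <- (p$value_a + p$value_b) / 2
  m <- mean(d)
  s <- sd(d)
  moa <- mean(avg)
  std <- if (moa == 0) NA_real_ else m / moa
  tibble(
    n = length(d), mean_diff = m, sd_diff = s,
    loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
    mean_of_averages = moa, std_mean_diff = std,
    status = if (moa == 0) "degenerate_zero_mean" else "ok"
  )
}

#' Root mean squared difference between paired measurements
#'
#' @param p Paired tibble with `value_a`, `value_b`.
#' @return `sqrt(mean((value_a - value_b)^2))`, in the measurement unit.
#' @export
paired_rmse <- function(p) {
  check_paired(p, min_n = 1)
  sqrt(mean((p$value_a - p$value_b)^2))
}

# Exact null distribution of the signed-rank statistic over 2^m sign flips,
# supporting tied (midrank) values: counts over doubled rank sums.
signed_rank_exact_p <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- c(1, rep(0, total))  # counts[s + 1] = #subsets with doubled sum s
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  w2 <- round(2 * w)
  p_le <- sum(counts[seq_len(w2 + 1)]) / 2^length(ranks)
  p_ge <- sum(counts[(w2 + 1):(total + 1)]) / 2^length(ranks)
  min(1, 2 * min(p_le, p_ge))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on `value_a - value_b`. Zero differences are dropped
#' (Wilcoxon's original treatment). With at most 25 nonzero differences the
#' exact null distribution is enumerated (a convolution over sign flips,
#' valid under midrank ties); above that a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param p Paired tibble with `value_a`, `value_b`.
#' @param exact_max Largest number of nonzero differences for which the
#'   exact distribution is enumerated (default 25).
#' @return One-row tibble: `statistic` (sum of positive-difference ranks),
#'   `p_value`, `n_nonzero`, `exact`, `degenerate` (`TRUE` with `p = 1`
#'   when all differences are zero).
#' @export
wilcoxon_signed_rank <- function(p, exact_max = 25) {
  check_paired(p, min_n = 1)
  d <- p$value_a - p$value_b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(tibble(statistic = NA_real_, p_value = 1, n_nonzero = 0L,
                  exact = NA, degenerate = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (m <= exact_max) {
    pv <- signed_rank_exact_p(w, r)
    exact <- TRUE
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    pv <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  tibble(statistic = w, p_value = pv, n_nonzero = m, exact = exact,
         degenerate = FALSE)
}

jt_statistic <- function(groups) {
  J <- 0
  ng <- length(groups)
  for (i in seq_len(ng - 1)) {
    for (j in (i + 1):ng) {
      x <- groups[[i]]
      y <- groups[[j]]
      cmp <- outer(x, y, "<")
      eq <- outer(x, y, "==")
      J <- J + sum(cmp) + 0.5 * sum(eq)
    }
  }
  J
}

# All assignments of `values` into groups of sizes `sizes`; calls fun on
# each list of groups. Used for the exact permutation null (small N only).
enumerate_assignments <- function(values, sizes, fun) {
  res <- c()
  recurse <- function(remaining, acc) {
    if (length(acc) == length(sizes)) {
      res <<- c(res, fun(acc))
      return(invisible())
    }
    gi <- length(acc) + 1L
    if (gi == length(sizes)) {
      recurse(numeric(0), c(acc, list(remaining)))
      return(invisible())
    }
    picks <- utils::combn(length(remaining), sizes[gi], simplify = FALSE)
    for (pk in picks) {
      recurse(remaining[-pk], c(acc, list(remaining[pk])))
    }
  }
  recurse(values, list())
  res
}

#' Jonckheere-Terpstra trend test for ordered groups
#'
#' Tests for an increase across ordered groups (e.g. drusen volume across
#' no AMD, early AMD, intermediate AMD). The statistic is
#' `J = sum over ordered group pairs of #(x < y) + 0.5 #(x = y)`. For total
#' sample size at most `exact_max` (default 10) the one-sided p-value is
#' computed by exhaustive enumeration of all group assignments; otherwise a
#' normal approximation with tie-corrected variance is used (no continuity
#' correction).
#'
#' @param groups List of numeric vectors in hypothesized increasing order,
#'   or a numeric vector together with `g`.
#' @param g Optional grouping factor (ordered by its levels) when `groups`
#'   is a numeric vector.
#' @param exact_max Largest total n for the exact permutation null.
#' @return One-row tibble: `statistic`, `p_value` (one-sided, increasing
#'   alternative), `n`, `exact`.
#' @export
jonckheere_terpstra <- function(groups, g = NULL, exact_max = 10) {
  if (!is.list(groups)) {
    if (is.null(g)) {
      abort_drusevol("Supply a list of groups or a grouping factor `g`.",
                     "drusevol_bad_groups")
    }
    groups <- split(groups, factor(g, levels = unique(as.character(
      if (is.factor(g)) levels(g) else g
    ))))
  }
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) {
    abort_drusevol("At least 2 non-empty groups are required.",
                   "drusevol_bad_groups")
  }
  J <- jt_statistic(groups)
  sizes <- lengths(groups)
  N <- sum(sizes)
  if (N <= exact_max) {
    pooled <- unlist(groups, use.names = FALSE)
    js <- enumerate_assignments(pooled, sizes, jt_statistic)
    pv <- mean(js >= J - 1e-9)
    exact <- TRUE
  } else {
    pooled <- unlist(groups, use.names = FALSE)
    t_j <- table(pooled)
    e_j <- (N^2 - sum(sizes^2)) / 4
    v <- (N * (N - 1) * (2 * N + 5) -
            sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
            sum(t_j * (t_j - 1) * (2 * t_j + 5))) / 72 +
      sum(sizes * (sizes - 1) * (sizes - 2)) *
        sum(t_j * (t_j - 1) * (t_j - 2)) /
        (36 * N * (N - 1) * (N - 2)) +
      sum(sizes * (sizes - 1)) * sum(t_j * (t_j - 1)) / (8 * N * (N - 1))
    if (v <= 0) {
      pv <- 0.5
    } else {
      pv <- pnorm((J - e_j) / sqrt(v), lower.tail = FALSE)
    }
    exact <- FALSE
  }
  tibble(statistic = J, p_value = pv, n = N, exact = exact)
}

#' Agreement on a high-progression-risk cut-off
#'
#' Classifies each eye per method as high-risk iff its volume is at or
#' above that method's cut-off, and summarizes the 2x2 table with Cohen's
#' kappa and raw percent agreement. Cut-offs differ per method because
#' volumes are not interchangeable across devices (e.g. 0.03 mm^3 on a
#' cube-scan device converts to 0.083 mm^3 on a dense raster scan).
#'
#' @param p Paired tibble with `value_a`, `value_b`.
#' @param cutoff_a,cutoff_b Positive per-method cut-offs (mm^3).
#' @return One-row tibble: `kappa`, `percent_agreement`, `n`, `status`
#'   (`"undefined_chance_agreement"` when expected agreement is 1 and kappa
#'   is undefined).
#' @export
kappa_high_risk <- function(p, cutoff_a, cutoff_b = cutoff_a) {
  check_paired(p, min_n = 1)
  if (cutoff_a <= 0 || cutoff_b <= 0) {
    abort_drusevol("Cut-offs must be positive.", "drusevol_bad_cutoff")
  }
  ha <- p$value_a >= cutoff_a
  hb <- p$value_b >= cutoff_b
  po <- mean(ha == hb)
  pe <- mean(ha) * mean(hb) + mean(!ha) * mean(!hb)
  if (pe >= 1) {
    return(tibble(kappa = NA_real_, percent_agreement = 100 * po,
                  n = length(ha), status = "undefined_chance_agreement"))
  }
  tibble(kappa = (po - pe) / (1 - pe), percent_agreement = 100 * po,
         n = length(ha), status = "ok")
}

#' Full agreement report for one method pair, by subgroup
#'
#' Computes, for each subgroup (`all`, the three AMD stages, and iAMD split
#' by RPD), the two-way ICCs, Bland-Altman summary, RMSE, paired Wilcoxon
#' p-value and - when cut-offs are supplied - high-risk kappa and percent
#' agreement. Subgroups too small or too uniform for an ICC carry its named
#' status instead of an estimate.
#'
#' @param p Paired tibble from [pair_measures()].
#' @param cutoff_a,cutoff_b Optional high-risk cut-offs per method (mm^3).
#' @param conf_level Confidence level for ICC intervals.
#' @return Tibble, one row per non-empty subgroup.
#' @export
agreement_report <- function(p, cutoff_a = NULL, cutoff_b = NULL,
                             conf_level = 0.95) {
  subsets <- list(
    all = rep(TRUE, nrow(p)),
    no_amd = p$stage == "no_amd",
    eamd = p$stage == "eamd",
    iamd = p$stage == "iamd",
    iamd_no_rpd = p$stage == "iamd" & !p$rpd,
    iamd_rpd = p$stage == "iamd" & p$rpd
  )
  rows <- list()
  for (nm in names(subsets)) {
    q <- p[subsets[[nm]], ]
    if (!nrow(q)) next
    icc_c <- try_icc(q, "consistency", conf_level)
    icc_a <- try_icc(q, "agreement", conf_level)
    ba <- if (nrow(q) >= 2) bland_altman(q) else
      tibble(mean_diff = NA_real_, sd_diff = NA_real_, loa_low = NA_real_,
             loa_high = NA_real_, std_mean_diff = NA_real_, status = "too_few")
    wil <- wilcoxon_signed_rank(q)
    row <- tibble(
      subgroup = nm, n = nrow(q),
      icc_consistency = icc_c$estimate,
      icc_consistency_low = icc_c$conf_low,
      icc_consistency_high = icc_c$conf_high,
      icc_agreement = icc_a$estimate,
      icc_agreement_low = icc_a$conf_low,
      icc_agreement_high = icc_a$conf_high,
      icc_status = icc_c$status,
      mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      std_mean_diff = ba$std_mean_diff,
      rmse = paired_rmse(q),
      wilcoxon_p = wil$p_value
    )
    if (!is.null(cutoff_a)) {
      kp <- kappa_high_risk(q, cutoff_a, cutoff_b %||% cutoff_a)
      row$kappa <- kp$kappa
      row$percent_agreement <- kp$percent_agreement
    }
    rows[[nm]] <- row
  }
  dplyr::bind_rows(rows)
}

try_icc <- function(q, type, conf_level) {
  res <- tryCatch(icc_two_way(q, type, conf_level), error = function(e) NULL)
  if (is.null(res)) {
    tibble(estimate = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
           status = "too_few")
  } else {
    res
  }
}
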