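#' Configure a full comparability study
#'
#' Bundles the simulation config with the measurement and analysis
#' settings: which floor algorithm each device's scans are measured with,
#' which device pairs are compared, per-method high-risk cut-offs, and the
#' circle/filter/resampling parameters.
#'
#' @param sim A [sim_cohort_config()].
#' @param algorithms Named character vector device -> `"bm_offset"` or
#'   `"rpe_fit"`. Defaults assign the expected-RPE fit to the cube-scan
#'   device and the BM-offset floor to the raster scans.
#' @param comparisons Named list of device-label pairs to compare
#'   (first label plays the reference role `value_a`).
#' @param high_risk_cutoffs Named per-device cut-offs (mm^3) for the kappa
#'   analysis. The defaults use 0.03 on the cube-scan scale and its
#'   converted 0.083 equivalent on the raster-scan scale.
#' @param target_row_spacing_um,min_height_px See [measure_eye()].
#' @param split_seed,train_frac Conversion train/test split settings.
#' @return A list of class `study_config`.
#' @export
study_config <- function(sim = sim_cohort_config(),
                         algorithms = c(spectralis_dense = "bm_offset",
                                        spectralis_sparse = "bm_offset",
                                        cirrus = "rpe_fit"),
                         comparisons = list(
                           inter_device = c("spectralis_dense", "cirrus"),
                           inter_scan = c("spectralis_dense",
                                          "spectralis_sparse")
                         ),
                         high_risk_cutoffs = c(spectralis_dense = 0.083,
                                               spectralis_sparse = 0.083,
                                               cirrus = 0.03),
                         target_row_spacing_um = 30,
                         min_height_px = 5,
                         split_seed = NULL,
                         train_frac = 0.8) {
  dev_names <- names(sim$devices)
  for (cmp in comparisons) {
    if (!all(cmp %in% dev_names)) {
      abort_drusevol("Comparison references an unconfigured device label.",
                     "drusevol_bad_config")
    }
  }
  structure(
    list(sim = sim, algorithms = algorithms, comparisons = comparisons,
         high_risk_cutoffs = high_risk_cutoffs,
         target_row_spacing_um = target_row_spacing_um,
         min_height_px = min_height_px,
         split_seed = split_seed %||% (sim$seed + 1L),
         train_frac = train_frac),
    class = "study_config"
  )
}

empty_agreement <- function() {
  tibble(comparison = character(), subgroup = character(), n = integer(),
         icc_consistency = double(), icc_consistency_low = double(),
         icc_consistency_high = double(), icc_agreement = double(),
         icc_agreement_low = double(), icc_agreement_high = double(),
         icc_status = character(), mean_diff = double(), sd_diff = double(),
         loa_low = double(), loa_high = double(), std_mean_diff = double(),
         rmse = double(), wilcoxon_p = double(), kappa = double(),
         percent_agreement = double())
}

#' Run a complete simulate -> segment -> quantify -> compare study
#'
#' Generates the cohort, measures every eye with its device's algorithm,
#' and produces: per-comparison, per-subgroup agreement reports; ROC
#' threshold analyses per method and case definition (early+intermediate,
#' early-only, intermediate-only AMD vs controls); the stage-trend test;
#' and the inter-device Deming conversion with optimal-subset selection
#' and train/test evaluation. Fully deterministic given the config.
#'
#' @param config A [study_config()].
#' @return A list of class `study_bundle`: `manifest`, `measurements`,
#'   `exclusions`, `agreement`, `roc`, `trend`, `conversion`, `log`.
#' @export
run_study <- function(config = study_config()) {
  cohort <- build_cohort(config$sim)
  meas <- measure_cohort(
    cohort,
    algorithms = config$algorithms,
    target_row_spacing_um = config$target_row_spacing_um,
    min_height_px = config$min_height_px
  )
  mm <- meas$measurements

  # Agreement per comparison x subgroup
  agreement <- empty_agreement()
  paired_list <- list()
  for (nm in names(config$comparisons)) {
    cmp <- config$comparisons[[nm]]
    p <- pair_measures(mm, cmp[1], cmp[2])
    paired_list[[nm]] <- p
    cuts <- config$high_risk_cutoffs
    rep_tbl <- agreement_report(
      p,
      cutoff_a = if (cmp[1] %in% names(cuts)) cuts[[cmp[1]]] else NULL,
      cutoff_b = if (cmp[2] %in% names(cuts)) cuts[[cmp[2]]] else NULL
    )
    if (nrow(rep_tbl)) {
      agreement <- dplyr::bind_rows(
        agreement, dplyr::bind_cols(tibble(comparison = nm), rep_tbl)
      )
    }
  }

  # ROC per method x case definition
  roc_rows <- list()
  roc_detail <- list()
  for (dev in unique(mm$method)) {
    sub <- mm[mm$method == dev, ]
    for (case_def in c("e_i_amd", "eamd_only", "iamd_only")) {
      sel <- switch(case_def,
        e_i_amd = rep(TRUE, nrow(sub)),
        eamd_only = sub$stage %in% c("no_amd", "eamd"),
        iamd_only = sub$stage %in% c("no_amd", "iamd")
      )
      q <- sub[sel, ]
      if (length(unique(q$stage == "no_amd")) < 2) next
      curve <- roc_points(q$volume_5mm_mm3, q$stage != "no_amd")
      opt <- optimal_threshold(curve)
      ss <- sens_spec_by_stage(sub$volume_5mm_mm3, sub$stage, opt$threshold)
      roc_detail[[paste(dev, case_def, sep = ".")]] <- curve
      roc_rows[[length(roc_rows) + 1L]] <- dplyr::bind_cols(
        tibble(method = dev, case_definition = case_def,
               auc = attr(curve, "auc")),
        opt,
        tidyr::pivot_wider(
          dplyr::select(ss, "stratum", "estimate"),
          names_from = "stratum", values_from = "estimate",
          names_prefix = "est_"
        )
      )
    }
  }
  roc_tbl <- if (length(roc_rows)) dplyr::bind_rows(roc_rows) else tibble()

  # Stage trend per method
  trend <- dplyr::bind_rows(lapply(unique(mm$method), function(dev) {
    sub <- mm[mm$method == dev, ]
    jt <- jonckheere_terpstra(
      sub$volume_5mm_mm3, factor(sub$stage, levels = amd_stages())
    )
    dplyr::bind_cols(tibble(method = dev), jt)
  }))

  # Inter-device conversion on iAMD eyes
  conversion <- NULL
  if ("inter_device" %in% names(paired_list)) {
    p_iamd <- dplyr::filter(paired_list$inter_device, .data$stage == "iamd")
    if (nrow(p_iamd) >= 10) {
      conversion <- fit_conversion(p_iamd, config$train_frac,
                                   config$split_seed)
    }
  }

  log <- list(
    seed = config$sim$seed,
    split_seed = config$split_seed,
    n_eyes_generated = nrow(cohort$manifest),
    n_measurements = nrow(mm),
    n_excluded = nrow(meas$exclusions),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("drusevol"))
  )

  structure(
    list(manifest = cohort$manifest, measurements = mm,
         exclusions = meas$exclusions, agreement = agreement,
         roc = roc_tbl, roc_curves = roc_detail, trend = trend,
         conversion = conversion, paired = paired_list, log = log),
    class = "study_bundle"
  )
}

# Deming conversion workflow on iAMD pairs: optimal-subset selection,
# seeded split, fits in both directions, test-set evaluation of the
# subset-trained fit against the whole-data-trained fit.
fit_conversion <- function(p_iamd, train_frac, split_seed) {
  split <- train_test_split(p_iamd, train_frac, split_seed)
  opt_train <- tryCatch(select_optimal_subset(split$train),
                        error = function(e) NULL)
  opt_test <- tryCatch(select_optimal_subset(split$test),
                       error = function(e) NULL)
  if (is.null(opt_train) || nrow(opt_train) < 3) return(NULL)

  # value_a = spectralis-like (raster), value_b = cirrus-like (cube)
  fit_s2c_whole <- deming_fit(split$train$value_a, split$train$value_b)
  fit_c2s_whole <- deming_fit(split$train$value_b, split$train$value_a)
  fit_s2c_opt <- deming_fit(opt_train$value_a, opt_train$value_b)
  fit_c2s_opt <- deming_fit(opt_train$value_b, opt_train$value_a)

  evals <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(fit = "whole", dataset = "whole_test"),
      evaluate_conversion(fit_c2s_whole, split$test,
                          from = "value_b", to = "value_a",
                          direction = "cirrus_to_spectralis")),
    dplyr::bind_cols(tibble(fit = "optimal", dataset = "whole_test"),
      evaluate_conversion(fit_c2s_opt, split$test,
                          from = "value_b", to = "value_a",
                          direction = "cirrus_to_spectralis")),
    dplyr::bind_cols(tibble(fit = "whole", dataset = "whole_test"),
      evaluate_conversion(fit_s2c_whole, split$test,
                          from = "value_a", to = "value_b",
                          direction = "spectralis_to_cirrus")),
    dplyr::bind_cols(tibble(fit = "optimal", dataset = "whole_test"),
      evaluate_conversion(fit_s2c_opt, split$test,
                          from = "value_a", to = "value_b",
                          direction = "spectralis_to_cirrus"))
  )
  if (!is.null(opt_test) && nrow(opt_test)) {
    evals <- dplyr::bind_rows(
      evals,
      dplyr::bind_cols(tibble(fit = "optimal", dataset = "optimal_test"),
        evaluate_conversion(fit_c2s_opt, opt_test,
                            from = "value_b", to = "value_a",
                            direction = "cirrus_to_spectralis")),
      dplyr::bind_cols(tibble(fit = "optimal", dataset = "optimal_test"),
        evaluate_conversion(fit_s2c_opt, opt_test,
                            from = "value_a", to = "value_b",
                            direction = "spectralis_to_cirrus"))
    )
  }
  list(
    n_iamd = nrow(p_iamd),
    n_train = nrow(split$train), n_test = nrow(split$test),
    n_optimal_train = nrow(opt_train),
    fits = list(spectralis_to_cirrus = fit_s2c_opt,
                cirrus_to_spectralis = fit_c2s_opt,
                spectralis_to_cirrus_whole = fit_s2c_whole,
                cirrus_to_spectralis_whole = fit_c2s_whole),
    evaluation = evals
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d eyes, %d measurements (%d excluded)\n",
              nrow(x$manifest), nrow(x$measurements), nrow(x$exclusions)))
  if (nrow(x$agreement)) {
    cat("Agreement (iAMD rows):\n")
    print(dplyr::filter(x$agreement, .data$subgroup == "iamd"))
  }
  invisible(x)
}

#' Write a study bundle to disk
#'
#' `format = "csv"` writes one CSV per table (manifest, measurements,
#' exclusions, agreement, ROC summary, trend) plus `conversion.json` and
#' `log.json`; `format = "json"` writes a single `report.json` that
#' round-trips losslessly through [jsonlite::read_json()].
#'
#' @param bundle A [run_study()] result.
#' @param dir Output directory (created if missing).
#' @param format `"csv"` or `"json"`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir, format = c("csv", "json")) {
  if (length(format) > 1) format <- format[1]
  if (!format %in% c("csv", "json")) {
    abort_drusevol(paste0("Unknown report format: ", format),
                   "drusevol_bad_format")
  }
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort_drusevol(paste0("Cannot create output directory: ", dir),
                   "drusevol_bad_path")
  }
  conv <- bundle$conversion
  conv_json <- if (is.null(conv)) NULL else list(
    n_iamd = conv$n_iamd, n_train = conv$n_train, n_test = conv$n_test,
    n_optimal_train = conv$n_optimal_train,
    fits = lapply(conv$fits, unclass),
    evaluation = conv$evaluation
  )
  if (format == "csv") {
    readr::write_csv(bundle$manifest, file.path(dir, "manifest.csv"))
    readr::write_csv(bundle$measurements, file.path(dir, "measurements.csv"))
    readr::write_csv(bundle$exclusions, file.path(dir, "exclusions.csv"))
    readr::write_csv(bundle$agreement, file.path(dir, "agreement.csv"))
    readr::write_csv(bundle$roc, file.path(dir, "roc_summary.csv"))
    readr::write_csv(bundle$trend, file.path(dir, "trend.csv"))
    jsonlite::write_json(conv_json, file.path(dir, "conversion.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(bundle$log, file.path(dir, "log.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(
      list(manifest = bundle$manifest, measurements = bundle$measurements,
           exclusions = bundle$exclusions, agreement = bundle$agreement,
           roc = bundle$roc, trend = bundle$trend, conversion = conv_json,
           log = bundle$log),
      file.path(dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(dir)
}
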