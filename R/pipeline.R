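# End-to-end orchestration: simulate (or load) -> preprocess -> normalize ->
# features -> group statistics -> discriminant models, with optional CSV/JSON
# output and a reproducibility manifest.

#' Full run configuration
#'
#' Bundles the cohort configuration with every tunable of the analysis. The
#' configuration is serialized verbatim into the run manifest so a run can be
#' reproduced from its report alone.
#'
#' @param cohort A [cohort_config()] (used when no input data are given).
#' @param sigma_ms Envelope Gaussian-smoothing sd (ms).
#' @param n_frames Amplitude-path envelope length.
#' @param band_low,band_high,notch_low,notch_high,filter_order Filter
#'   settings (Hz).
#' @param alpha Significance level of the group tests.
#' @param alpha_norm Shapiro-Wilk gate level.
#' @param p_enter,p_remove Stepwise entry/removal thresholds.
#' @param notch_waveform Apply the 50 Hz band-stop on the waveform path too.
#' @param p_adjust `"none"` (default) or `"BH"` across the comparison grid.
#' @param strict_loocv Re-run stepwise selection inside every fold.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), sigma_ms = 50,
                       n_frames = 1000L, band_low = 25, band_high = 500,
                       notch_low = 49.5, notch_high = 50.5, filter_order = 4,
                       alpha = 0.05, alpha_norm = 0.05,
                       p_enter = 0.05, p_remove = 0.10,
                       notch_waveform = FALSE, p_adjust = "none",
                       strict_loocv = FALSE) {
  structure(list(cohort = cohort, sigma_ms = sigma_ms, n_frames = n_frames,
                 band_low = band_low, band_high = band_high,
                 notch_low = notch_low, notch_high = notch_high,
                 filter_order = filter_order, alpha = alpha,
                 alpha_norm = alpha_norm, p_enter = p_enter,
                 p_remove = p_remove, notch_waveform = notch_waveform,
                 p_adjust = p_adjust, strict_loocv = strict_loocv),
            class = "run_config")
}

# candidate variable pools per classifier family, in tie-break order
# (amplitude before waveform, ascending sensor)
.candidate_pool <- function(family, n_sensors) {
  s <- seq_len(n_sensors)
  amp <- function(m) c(rbind(paste0("M_", m, s), paste0("R_", m, s)))
  wave <- c(rbind(paste0("NZC", s), paste0("EWL", s)))
  switch(family,
         MAX = amp("MAX"), MVC = amp("MVC"), GRASP = amp("GRASP"),
         Waveform = wave, NoMVC = c(amp("MAX"), wave),
         stop("unknown model family ", family))
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort, preprocesses both signal paths, computes
#' normalization values, amplitude and waveform feature tables with
#' task-averaged participant summaries, the overall and per-task group
#' comparisons with sign matrices, the mixed repeated-measures ANOVA on the
#' normalization values with Tukey's-B sensor subsets, and then fits one
#' stepwise discriminant model per family (MAX, MVC, GRASP, Waveform, NoMVC)
#' with leave-one-out cross-validation, restricting candidates to the
#' variables that differed significantly between groups. Identical
#' configuration and seed give identical results (and manifest hashes, when
#' written).
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built `semg_cohort` (skips simulation).
#' @param output_dir Optional directory: writes the CSV tables, model JSON,
#'   and a manifest with content hashes.
#' @return An `semg_analysis` list; see the elements in the description.
#' @export
run_full_analysis <- function(config = run_config(), cohort = NULL,
                              output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)

  processed <- preprocess_cohort(cohort,
                                 sigma_ms = config$sigma_ms,
                                 n_frames = config$n_frames,
                                 notch_waveform = config$notch_waveform,
                                 band_low = config$band_low,
                                 band_high = config$band_high,
                                 notch_low = config$notch_low,
                                 notch_high = config$notch_high,
                                 order = config$filter_order)
  norms <- normalization_table(processed)
  amp <- amplitude_feature_table(processed, norms)
  wave <- waveform_feature_table(processed)
  summary_tbl <- participant_summary(amp, wave)

  comparisons <- compare_all_variables(summary_tbl, alpha = config$alpha,
                                       alpha_norm = config$alpha_norm,
                                       p_adjust = config$p_adjust)
  amp_task <- per_task_comparisons(amp, c("median", "range"),
                                   alpha = config$alpha,
                                   alpha_norm = config$alpha_norm)
  wave_task <- per_task_comparisons(wave, c("nzc_rescaled", "ewl_rescaled"),
                                    alpha = config$alpha,
                                    alpha_norm = config$alpha_norm)
  signs <- list(amplitude = build_sign_table(amp_task),
                waveform = build_sign_table(wave_task))
  rm_anova <- mixed_rm_anova(norms)
  sens_row <- rm_anova[rm_anova$effect == "sensor", ]
  sensor_means <- tapply((norms$max_mV + norms$mvc_mV + norms$grasp_mV) / 3,
                         norms$sensor, mean)
  tukey_sensors <- tukeys_b_subsets(sensor_means,
                                    ms_error = sens_row$ms_error[1L],
                                    df_error = sens_row$df_error[1L],
                                    n = 3L * length(unique(norms$participant_id)))

  sig_vars <- comparisons$variable[comparisons$p_value < config$alpha]
  n_sensors <- max(norms$sensor)
  models <- list()
  for (fam in c("MAX", "MVC", "GRASP", "Waveform", "NoMVC")) {
    pool <- intersect(.candidate_pool(fam, n_sensors), sig_vars)
    if (length(pool) == 0L) {
      models[[fam]] <- list(
        model = structure(list(no_model = TRUE, selected = character(0),
                               lambda = NA_real_, lambda_trace = numeric(0),
                               reason = "no significant candidate variables"),
                          class = "discriminant_model"),
        box_m = NULL, cv = NULL)
      next
    }
    bm <- tryCatch(boxs_m_test(summary_tbl[, pool, drop = FALSE],
                               summary_tbl$group),
                   error = function(e) NULL)
    if (!is.null(bm) && bm$p_value <= 0.05) {
      warning("Box's M rejects covariance homogeneity for family ", fam,
              " (p = ", signif(bm$p_value, 3), "); proceeding")
    }
    m <- stepwise_lda(summary_tbl, pool, p_enter = config$p_enter,
                      p_remove = config$p_remove)
    cv <- if (!isTRUE(m$no_model)) {
      loocv(summary_tbl, m$selected, strict = config$strict_loocv,
            candidates = pool, p_enter = config$p_enter,
            p_remove = config$p_remove)
    } else NULL
    models[[fam]] <- list(model = m, box_m = bm, cv = cv)
  }

  result <- structure(list(config = config,
                           ground_truth = cohort$ground_truth,
                           normalization = norms,
                           amplitude_features = amp,
                           waveform_features = wave,
                           summary = summary_tbl,
                           comparisons = comparisons,
                           per_task = list(amplitude = amp_task,
                                           waveform = wave_task),
                           sign_matrices = signs,
                           rm_anova = rm_anova,
                           tukey_sensors = tukey_sensors,
                           models = models),
                      class = "semg_analysis")
  if (!is.null(output_dir)) .write_analysis(result, output_dir)
  result
}

#' @export
print.semg_analysis <- function(x, ...) {
  cat("<semg_analysis> ", nrow(x$summary), " participants, ",
      sum(x$comparisons$p_value < x$config$alpha), "/",
      nrow(x$comparisons), " variables significant\n", sep = "")
  for (fam in names(x$models)) {
    m <- x$models[[fam]]
    if (isTRUE(m$model$no_model)) {
      cat(sprintf("  %-9s no model\n", fam))
    } else {
      cat(sprintf("  %-9s vars: %s | LOOCV acc %.1f%% (sens %.1f%%, spec %.1f%%)\n",
                  fam, paste(m$model$selected, collapse = ", "),
                  m$cv$accuracy, m$cv$sensitivity, m$cv$specificity))
    }
  }
  invisible(x)
}

# serialize run config (drops classes for JSON)
.config_as_list <- function(config) {
  cl <- unclass(config)
  cl$cohort <- unclass(cl$cohort)
  cl$cohort$effect <- unclass(cl$cohort$effect)
  cl
}

.write_analysis <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    readr::write_csv(df, file.path(output_dir, name))
    name
  }
  files <- c(
    wr(result$normalization, "normalization_values.csv"),
    wr(result$amplitude_features, "amplitude_features.csv"),
    wr(result$waveform_features, "waveform_features.csv"),
    wr(result$summary, "participant_summary.csv"),
    wr(result$comparisons, "group_comparisons.csv"),
    wr(result$per_task$amplitude, "per_task_amplitude.csv"),
    wr(result$per_task$waveform, "per_task_waveform.csv"),
    wr(result$rm_anova[, setdiff(names(result$rm_anova), "fit")],
       "rm_anova.csv"))
  for (nm in names(result$sign_matrices)) {
    f <- paste0("sign_matrix_", nm, ".txt")
    m <- result$sign_matrices[[nm]]
    utils::write.table(unclass(m), file.path(output_dir, f), quote = FALSE,
                       sep = "\t", col.names = NA)
    files <- c(files, f)
  }
  models_json <- lapply(result$models, function(m) {
    list(no_model = isTRUE(m$model$no_model),
         selected = m$model$selected,
         coefficients = as.list(m$model$coefficients),
         constant = m$model$constant,
         sign_convention = m$model$sign_convention,
         wilks_lambda = m$model$lambda,
         box_m = m$box_m,
         cv = if (!is.null(m$cv)) {
           m$cv$folds <- NULL
           unclass(m$cv)
         })
  })
  jsonlite::write_json(models_json, file.path(output_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, "models.json")
  manifest <- list(
    config = .config_as_list(result$config),
    seed = result$config$cohort$seed,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(output_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(output_dir)
}
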