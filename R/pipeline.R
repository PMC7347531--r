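#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. By default the
#' pipeline generates the synthetic cohort described by `cohort`; passing
#' `input_dir` (a directory written by [write_cohort()]) analyzes existing
#' records instead.
#'
#' @param cohort a [cohort_spec()].
#' @param input_dir optional directory with `manifest.csv` and signal CSVs.
#' @param pspr a [pspr_config()].
#' @param alpha_remove stepwise retention threshold.
#' @param cv_k integer vector of fold counts for the cross-validation stage
#'   (`NULL` skips it).
#' @param cv_repeats repeats per fold count.
#' @param cv_seed seed of the cross-validation splits (defaults to the
#'   cohort's `global_seed`).
#' @param out_dir optional output directory; when set, all intermediate
#'   tables (CSV) and the run report (JSON) are written there.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), input_dir = NULL,
                            pspr = pspr_config(), alpha_remove = 0.05,
                            cv_k = 2:24, cv_repeats = 100, cv_seed = NULL,
                            out_dir = NULL) {
  structure(list(
    cohort = cohort, input_dir = input_dir, pspr = pspr,
    alpha_remove = alpha_remove, cv_k = cv_k, cv_repeats = cv_repeats,
    cv_seed = cv_seed %||% cohort$global_seed, out_dir = out_dir
  ), class = "pipeline_config")
}

stage <- function(name, subject, expr) {
  tryCatch(expr, error = function(e) {
    stop_("pipeline stage '%s' failed%s: %s", name,
          if (nzchar(subject)) sprintf(" (subject %s)", subject) else "",
          conditionMessage(e))
  })
}

#' Run the full study-analogue pipeline
#'
#' Executes every stage in order: cohort generation (or ingestion),
#' preprocessing (8 Hz downsampling and R-peak detection), HR
#' characteristics, reference-based PSPR features (prevalent-group records
#' are used exclusively as references and never enter the classifier),
#' univariate group statistics, the backward-elimination logistic fit
#' distinguishing prodromal from control, and the repeated k-fold
#' cross-validation curve. All stages are deterministic given the
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pspr_run` holding the configuration echo,
#'   manifest, HRV table, feature table, group-statistics tables, fit
#'   summary and CV curve.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(cohort = cohort_spec(n_control = 12, n_prodromal = 12,
#'                                             n_prevalent = 4),
#'                        cv_k = 2:3, cv_repeats = 2)
#' run <- run_pipeline(cfg)
#' run
#' }
run_pipeline <- function(config) {
  cohort <- stage("cohort", "", {
    if (is.null(config$input_dir)) generate_cohort(config$cohort)
    else read_cohort(config$input_dir)
  })
  manifest <- cohort$manifest
  if (!nrow(manifest)) stop_("pipeline stage 'cohort' failed: empty cohort")

  records <- cohort$records
  series8 <- lapply(names(records), function(id) {
    stage("downsample", id, downsample_to_8hz(records[[id]]))
  })
  names(series8) <- names(records)

  hrv_rows <- lapply(names(records), function(id) {
    stage("hrv", id, {
      peaks <- detect_r_peaks(records[[id]])
      stats::setNames(
        as.list(hr_characteristics(instantaneous_hr(peaks))),
        paste0("hr_", hr_feature_names))
    })
  })
  hrv_table <- cbind(manifest[, c("subject_id", "group")],
                     do.call(rbind, lapply(hrv_rows, as.data.frame)))
  rownames(hrv_table) <- NULL

  ref_ids <- manifest$subject_id[manifest$group == "prevalent"]
  tgt_ids <- manifest$subject_id[manifest$group %in% c("control", "prodromal")]
  if (!length(ref_ids)) stop_("pipeline stage 'pspr' failed: no prevalent reference records")

  feats <- stage("pspr", "", {
    pspr_feature_matrix(series8[tgt_ids], series8[ref_ids], config$pspr)
  })

  feature_table <- data.frame(
    subject_id = tgt_ids,
    label = as.integer(manifest$group[match(tgt_ids, manifest$subject_id)] == "prodromal"),
    feats,
    hrv_table[match(tgt_ids, hrv_table$subject_id),
              paste0("hr_", hr_feature_names)],
    row.names = NULL, check.names = FALSE
  )

  feat_cols <- c(colnames(feats), paste0("hr_", hr_feature_names))
  two_group <- stage("group_stats", "", {
    dat <- feature_table
    dat$group <- ifelse(dat$label == 1, "prodromal", "control")
    compare_groups(dat, feat_cols, "group")
  })
  three_group_hrv <- stage("group_stats", "", {
    compare_groups(hrv_table, paste0("hr_", hr_feature_names), "group")
  })

  # high pattern lengths can be constant in small cohorts (every context
  # unshared: the dissimilarity sits exactly at its saturation value);
  # constant columns carry no information and are excluded from the model
  const <- vapply(feat_cols, function(f) stats::sd(feature_table[[f]]) == 0,
                  logical(1))
  if (any(const)) {
    warn_("constant feature(s) excluded from the classifier: %s",
          paste(feat_cols[const], collapse = ", "))
  }
  model_cols <- feat_cols[!const]
  fml <- stats::as.formula(paste("label ~", paste(sprintf("`%s`", model_cols), collapse = " + ")))
  fit <- stage("fit", "", backward_lr(fml, feature_table, config$alpha_remove))

  cv <- if (!is.null(config$cv_k)) {
    stage("cv", "", cv_curve(fml, feature_table, k_range = config$cv_k,
                             n_repeats = config$cv_repeats,
                             seed = config$cv_seed,
                             alpha_remove = config$alpha_remove))
  }

  run <- structure(list(
    package_version = as.character(utils::packageVersion("psprecg")),
    config = config,
    manifest = manifest,
    hrv_table = hrv_table,
    feature_table = feature_table,
    group_stats = list(prodromal_vs_control = two_group,
                       hrv_three_group = three_group_hrv),
    fit = fit,
    cv = cv
  ), class = "pspr_run")

  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(run$hrv_table, file.path(dir, "hrv_features.csv"), row.names = FALSE)
  utils::write.csv(run$feature_table, file.path(dir, "feature_table.csv"), row.names = FALSE)
  utils::write.csv(run$group_stats$prodromal_vs_control,
                   file.path(dir, "group_stats_prodromal_vs_control.csv"), row.names = FALSE)
  utils::write.csv(run$group_stats$hrv_three_group,
                   file.path(dir, "group_stats_hrv_three_group.csv"), row.names = FALSE)
  if (!is.null(run$cv)) {
    utils::write.csv(as.data.frame(run$cv), file.path(dir, "cv_curve.csv"), row.names = FALSE)
  }
  report <- list(
    package_version = run$package_version,
    config = list(
      n_control = run$config$cohort$n_control,
      n_prodromal = run$config$cohort$n_prodromal,
      n_prevalent = run$config$cohort$n_prevalent,
      global_seed = run$config$cohort$global_seed,
      n_s = run$config$pspr$n_s, n_p = run$config$pspr$n_p,
      binning = run$config$pspr$binning,
      alpha_remove = run$config$alpha_remove,
      cv_k = run$config$cv_k, cv_repeats = run$config$cv_repeats,
      cv_seed = run$config$cv_seed
    ),
    fit = list(
      selected = run$fit$selected,
      coefficients = as.list(run$fit$coefficients),
      auc = run$fit$auc, auc_ci = run$fit$auc_ci,
      sensitivity = run$fit$sensitivity, specificity = run$fit$specificity,
      separable = run$fit$separable,
      trace = run$fit$trace
    ),
    cv = if (!is.null(run$cv)) as.data.frame(run$cv)
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pspr_run <- function(x, ...) {
  tab <- table(factor(x$manifest$group, levels = cohort_groups))
  cat("PSPR ECG pipeline run\n")
  cat(sprintf("  cohort: %s\n",
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  feature table: %d subjects x %d features\n",
              nrow(x$feature_table), ncol(x$feature_table) - 2))
  sig <- x$group_stats$prodromal_vs_control
  cat(sprintf("  significant features (prodromal vs control): %d of %d\n",
              sum(sig$significant), nrow(sig)))
  print(x$fit)
  if (!is.null(x$cv)) {
    i5 <- match(5, x$cv$k)
    if (!is.na(i5)) {
      cat(sprintf("  5-fold CV AUC %.3f [%.3f, %.3f] over %d repeats\n",
                  x$cv$mean_auc[i5], x$cv$ci_low[i5], x$cv$ci_high[i5],
                  x$cv$n_repeats))
    }
  }
  invisible(x)
}
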