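#' Default end-to-end run configuration
#'
#' Nested configuration for the full pipeline. Every default is either a
#' stated processing constant of the method (20--450 Hz band, 60 Hz notch,
#' 18 dB gate, 101-point cycles, k = 15 features, 80/20 split, 5-fold CV) or
#' a documented package decision (see the methods vignette). Serializes
#' losslessly to JSON via [write_config()] / [read_config()].
#'
#' @param seed root seed; per-stage seeds are derived from it.
#' @param out_dir output directory for [run_pipeline()].
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = "emgoa-run") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synthetic = list(n_subjects = 75, limbs_per_subject = 2, trials_per_limb = 5,
                     cycles_per_trial = 6, fs = 1500, severity_effect_cci = 0.6,
                     severity_effect_g = 0.8, line_noise_amp = 0.2,
                     artifact_prob = 0.02, prom_noise_sd = 0.5),
    preprocessing = list(snr_threshold_db = 18),
    features = list(divisor = "count"),
    model = list(k_features = 15, test_fraction = 0.20, cv_folds = 5,
                 depth_grid = c(3, 5, 7, 9, 12), n_trees = 500, min_node = 5,
                 grouped_split = TRUE),
    shap = list(background_size = 50, enumeration_bound = 15)
  ), class = "run_config")
}

#' @rdname default_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(cfg[[nm]])) base[[nm]][[k]] <- cfg[[nm]][[k]]
    } else base[[nm]] <- cfg[[nm]]
  }
  base
}

#' Fingerprint of the semantic content of a configuration
#'
#' @param config a `run_config`.
#' @return md5 hex string; changes iff any semantic field changes.
#' @export
config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write / read a feature table as CSV
#'
#' Comma-separated, UTF-8, header row, '.' decimal; feature names (which
#' contain '-') are preserved verbatim. A JSON sidecar records column roles.
#'
#' @param tbl feature table.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(tbl, path) {
  write.csv(tbl, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".columns.json", path)
  jsonlite::write_json(list(identifiers = c("subject_id", "limb", "latent_severity"),
                            predictors = predictor_columns(tbl),
                            targets = c("womac_total", "pain", "stiffness",
                                        "physical_function", "vas")),
                       sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- read.csv(path, check.names = FALSE)
  required <- c("subject_id", "limb", "womac_total", "pain", "stiffness",
                "physical_function", "vas")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0)
    stop(sprintf("feature table schema mismatch: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  tbl
}

#' Write a synthetic cohort to delimited text files
#'
#' Per limb and trial: a wide EMG CSV (`time_s, RF, MH, TA, G`) and an events
#' CSV (`cycle_index, heel_strike_s, toe_off_s, next_heel_strike_s`); per
#' cohort: a temporospatial CSV, a PROM CSV (subject, limb, 24 item columns,
#' vas) and a JSON manifest. Raw EMG files are large; intended for CLI
#' interoperability, not for test fixtures.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param write_raw write the per-trial raw EMG CSVs (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_raw = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prom_rows <- list()
  ts_rows <- list()
  manifest <- list()
  for (subj in cohort) {
    for (lb in subj$limbs) {
      key <- sprintf("%s_%s", subj$subject_id, lb$limb)
      for (i in seq_along(lb$trials)) {
        tr <- lb$trials[[i]]
        ev <- lb$events[[i]]
        if (write_raw) {
          n <- nrow(tr$signals)
          emg <- data.frame(time_s = (seq_len(n) - 1) / tr$fs, tr$signals,
                            check.names = FALSE)
          write.csv(emg, file.path(dir, sprintf("%s_trial%02d_emg.csv", key, i)),
                    row.names = FALSE)
        }
        nc <- length(ev$toe_offs)
        write.csv(data.frame(cycle_index = seq_len(nc),
                             heel_strike_s = ev$heel_strikes[seq_len(nc)],
                             toe_off_s = ev$toe_offs,
                             next_heel_strike_s = ev$heel_strikes[-1]),
                  file.path(dir, sprintf("%s_trial%02d_events.csv", key, i)),
                  row.names = FALSE)
      }
      ts_rows[[key]] <- data.frame(subject_id = subj$subject_id, limb = lb$limb,
                                   stride_length_m = lb$stride_length_m,
                                   step_length_m = lb$step_length_m)
      items <- as.list(subj$prom$womac_items)
      names(items) <- sprintf("item%02d", 1:24)
      prom_rows[[key]] <- data.frame(subject_id = subj$subject_id, limb = lb$limb,
                                     items, vas = subj$prom$vas)
      manifest[[key]] <- list(subject_id = subj$subject_id, limb = lb$limb,
                              trials = length(lb$trials),
                              latent_severity = subj$latent_severity)
    }
  }
  write.csv(do.call(rbind, ts_rows), file.path(dir, "temporospatial.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, prom_rows), file.path(dir, "prom.csv"),
            row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full pipeline: simulate, preprocess, features, severity, fit, explain
#'
#' Executes all six stages on a synthetic cohort under one root seed and
#' writes the stage artifacts (features CSV, severity labels CSV, group
#' summary CSV, regression report JSON, attribution and importance CSVs) plus
#' a run manifest with config fingerprint, stage timings and artifact
#' checksums into `config$out_dir`. Re-running with the same config
#' reproduces identical feature tables and reports.
#'
#' @param config a `run_config` from [default_config()].
#' @return the manifest, invisibly; stage outputs on disk.
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  syn <- config$synthetic
  spec <- stage("simulate", {
    do.call(cohort_spec, c(syn, list(seed = config$seed)))
  })
  cohort <- stage("simulate_cohort", generate_cohort(spec))

  tbl <- stage("preprocess_features",
               cohort_feature_table(cohort,
                                    threshold_db = config$preprocessing$snr_threshold_db,
                                    divisor = config$features$divisor))
  f_path <- file.path(config$out_dir, "features.csv")
  write_feature_table(tbl, f_path)

  labels <- stage("severity", {
    cuts <- midpoint_cutoffs(24)
    data.frame(subject_id = tbl$subject_id, limb = tbl$limb,
               womac_total = tbl$womac_total, vas = tbl$vas,
               womac_class = categorize_severity(tbl$womac_total,
                                                 cuts["low"], cuts["high"]),
               vas_class = categorize_vas(tbl$vas))
  })
  write.csv(labels, file.path(config$out_dir, "severity_labels.csv"),
            row.names = FALSE)
  summary_tbl <- severity_group_summary(tbl)
  write.csv(summary_tbl, file.path(config$out_dir, "group_summary.csv"),
            row.names = FALSE)

  cfg_model <- do.call(model_config, c(config$model, list(seed = config$seed + 1000L)))
  report <- stage("fit", run_all_targets(tbl, cfg_model))
  report_json <- lapply(report, function(r)
    list(target = r$target, selected_features = r$selected_features,
         chosen_depth = r$chosen_depth, cv_r2 = r$cv_r2,
         cv_curve = r$cv_curve, test_r2 = r$test$r2, rmse = r$test$rmse,
         pearson_r = r$test$pearson_r))
  jsonlite::write_json(report_json, file.path(config$out_dir, "regression_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (tg in names(report))
    write.csv(data.frame(actual = report[[tg]]$actual,
                         predicted = report[[tg]]$predicted),
              file.path(config$out_dir, sprintf("scatter_%s.csv", tg)),
              row.names = FALSE)

  shap_out <- stage("explain", {
    out <- list()
    for (tg in names(report)) {
      r <- report[[tg]]
      xtr <- tbl[r$split$train, r$selected_features, drop = FALSE]
      set.seed(config$seed + 2000L)
      bg <- xtr[sample(nrow(xtr), min(config$shap$background_size, nrow(xtr))), ,
                drop = FALSE]
      xall <- tbl[, r$selected_features, drop = FALSE]
      ts <- tree_shap(r$model, xall, bg)
      write.csv(data.frame(subject_id = tbl$subject_id, limb = tbl$limb, ts$phi,
                           check.names = FALSE),
                file.path(config$out_dir, sprintf("shap_%s.csv", tg)),
                row.names = FALSE)
      gi <- global_importance(ts$phi)
      write.csv(gi$top, file.path(config$out_dir, sprintf("importance_%s.csv", tg)),
                row.names = FALSE)
      out[[tg]] <- list(importance = gi, summary = shap_summary_table(ts$phi, xall))
    }
    jsonlite::write_json(lapply(out, function(o) utils::head(o$summary, 10)),
                         file.path(config$out_dir, "shap_top10.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
  })

  artifacts <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    config_fingerprint = config_fingerprint(config),
    seed = config$seed,
    stages = names(timings),
    timings_s = timings,
    n_limbs = nrow(tbl),
    checksums = as.list(tools::md5sum(artifacts))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, features = tbl, report = report,
                 shap = shap_out, labels = labels, group_summary = summary_tbl))
}
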