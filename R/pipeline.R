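# End-to-end pipeline on a synthetic cohort: simulate -> median beats ->
# split -> normalize -> train FCN -> predict -> recalibrate -> evaluate
# (including classical voltage criteria) -> explain.

# Polynomial rolling hash of a serialized object (exact in double
# precision); stamps pipeline artifacts so runs from different
# configurations are not accidentally mixed.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  m <- 2147483629
  for (b in bytes) h <- (h * 257 + b) %% m
  sprintf("%08x", h)
}

#' Run the full synthetic-cohort LVH pipeline
#'
#' Chains every stage of the analysis on a synthetic cohort: ECG
#' simulation, median-beat extraction, cohort splitting, metadata
#' normalization (training split only), FCN training for iLVM
#' regression, prediction, logistic recalibration into sex-specific LVH
#' decisions, reference-threshold and voltage-criteria benchmarks, the
#' full evaluation report on the held-out test split, and (optionally)
#' integrated-gradients explainability summaries. Deterministic for a
#' given (config, seed).
#'
#' @param config a [synthetic_cohort_config()].
#' @param seed integer master seed for splitting, training and
#'   evaluation randomness (the cohort itself is governed by
#'   `config$seed`).
#' @param include_metadata include the 15-entry clinical metadata vector
#'   in the model input (`FALSE` gives the ECG-only ablation variant).
#' @param model_fs network input rate, Hz.
#' @param split_fractions train/validation/test fractions.
#' @param max_epochs,batch_size,learning_rate training-loop settings
#'   passed to [fcn_train_config()].
#' @param n_boot bootstrap replicates in the evaluation report.
#' @param explain_n number of test participants to attribute with
#'   integrated gradients (0 skips explainability).
#' @param ig_background,ig_steps integrated-gradients baseline count and
#'   path steps.
#' @param out_dir optional directory for artifacts (predictions CSV,
#'   training history CSV, evaluation report JSON); each artifact is
#'   stamped with the configuration hash.
#' @param verbose print per-stage progress.
#' @return list of class `lvh_pipeline_result` with the cohort tables,
#'   split, median-beat summaries, trained model and history,
#'   predictions, recalibration, evaluation reports and explainability
#'   summaries.
#' @export
run_lvh_pipeline <- function(config = synthetic_cohort_config(),
                             seed = 1L, include_metadata = TRUE,
                             model_fs = 100,
                             split_fractions = c(0.7, 0.15, 0.15),
                             max_epochs = 30, batch_size = 64,
                             learning_rate = 5e-4, n_boot = 1000,
                             explain_n = 0, ig_background = 32,
                             ig_steps = 25, out_dir = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  t0 <- proc.time()[3]
  say <- function(fmt, ...) if (verbose) {
    message(sprintf("[%6.1fs] %s", proc.time()[3] - t0, sprintf(fmt, ...)))
  }

  say("simulating cohort (n = %d, preset %s)", config$n_participants, config$preset)
  tables <- cohort_tables(config)
  n <- config$n_participants

  say("extracting median beats")
  beats <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    pe <- participant_ecg(config, tables, i)
    mb <- tryCatch(extract_median_beat(pe$raw_ecg),
                   ecglvh_extraction_failure = function(e) NULL)
    if (!is.null(mb)) {
      beats[[i]] <- mb
      ok[i] <- TRUE
    }
  }
  if (sum(ok) < n) {
    warning(sprintf("median-beat extraction failed for %d participant(s); excluded",
                    n - sum(ok)), call. = FALSE)
  }
  clinical <- impute_missing(tables$clinical[ok, , drop = FALSE])
  cmr <- tables$cmr[ok, , drop = FALSE]
  beats <- beats[ok]
  ids <- cmr$participant_id
  rate <- vapply(beats, `[[`, numeric(1), "ventricular_rate_bpm")

  say("splitting cohort")
  split <- split_cohort(ids, split_fractions, seed = derive_seed(seed, 2L))
  part <- rep("train", length(ids))
  part[ids %in% split$validation_ids] <- "validation"
  part[ids %in% split$test_ids] <- "test"

  md <- metadata_features(clinical, ventricular_rate_bpm = rate)
  stats <- fit_normalization(md[part == "train", , drop = FALSE])
  mdn <- normalize_features(md, stats)

  say("assembling model inputs (model rate %g Hz)", model_fs)
  wf <- simplify2array(lapply(beats, function(b) {
    if (!is.null(model_fs) && model_fs != b$sampling_rate_hz) {
      resample_beat(b$waveforms, b$sampling_rate_hz, model_fs)
    } else b$waveforms
  }))
  feats <- structure(list(ecg = wf, metadata = mdn, y = cmr$ilvm, ids = ids),
                     class = "fcn_features")
  idx_of <- function(p) which(part == p)
  tr <- subset_features(feats, idx_of("train"))
  va <- subset_features(feats, idx_of("validation"))

  say("training FCN (%d train / %d val)", length(tr$y), length(va$y))
  mcfg <- fcn_config(beat_length = dim(wf)[1],
                     metadata_dim = if (include_metadata) ncol(mdn) else 0L)
  model <- build_fcn(mcfg, seed = derive_seed(seed, 3L))
  tcfg <- fcn_train_config(learning_rate = learning_rate,
                           batch_size = batch_size, max_epochs = max_epochs,
                           seed = derive_seed(seed, 4L))
  fit <- train_model(model, tr, va, tcfg, verbose = verbose)
  model <- fit$model

  say("predicting and recalibrating")
  pred <- predict(model, feats)
  sexes <- cmr$sex
  fit_idx <- part != "test"
  recal <- fit_recalibration(pred[fit_idx], sexes[fit_idx], cmr$lvh_label[fit_idx])
  prob <- predict(recal, pred, sexes)
  ref_label <- classify_by_reference_threshold(pred, sexes)

  say("benchmark voltage criteria on the test split")
  test_i <- idx_of("test")
  sl <- vapply(test_i, function(i) sokolow_lyon(measure_wave_amplitudes(beats[[i]]))$positive, logical(1))
  cv <- vapply(test_i, function(i) cornell_voltage(measure_wave_amplitudes(beats[[i]]), sexes[i])$positive, logical(1))

  say("evaluation on the held-out test split (n = %d)", length(test_i))
  y_test <- cmr$lvh_label[test_i]
  if (length(unique(y_test)) < 2) {
    warning("test split contains a single class; classification report omitted",
            call. = FALSE)
    report <- NULL
  } else {
  report <- evaluation_report(prob[test_i], y_test,
                              predicted_ilvm = pred[test_i],
                              observed_ilvm = cmr$ilvm[test_i],
                              comparator = list(name = "predicted_ilvm_direct",
                                                scores = pred[test_i]),
                              n_boot = n_boot, seed = derive_seed(seed, 5L))
  }
  benchmark <- if (any(y_test) && !all(y_test)) {
    list(
      reference_threshold = binary_metrics(as.numeric(ref_label[test_i]), as.numeric(y_test)),
      sokolow_lyon = binary_metrics(as.numeric(sl), as.numeric(y_test)),
      cornell_voltage = binary_metrics(as.numeric(cv), as.numeric(y_test))
    )
  } else NULL

  explain <- NULL
  if (explain_n > 0) {
    say("integrated gradients (%d participants, %d baselines)", explain_n, ig_background)
    bg_i <- with_seed(derive_seed(seed, 6L),
                      sample(test_i, min(ig_background, length(test_i))))
    bg <- subset_features(feats, bg_i)
    pick <- test_i[order(-pred[test_i])][seq_len(min(explain_n, length(test_i)))]
    maps <- lapply(pick, function(i) {
      integrated_gradients(model,
                           list(ecg = feats$ecg[, , i],
                                metadata = setNames(feats$metadata[i, ], colnames(feats$metadata))),
                           bg, steps = ig_steps)
    })
    groups <- percentile_group_waveforms(pred, wf)
    explain <- list(maps = maps,
                    metadata_importance = metadata_importance_summary(maps),
                    percentile_groups = groups)
  }

  result <- structure(list(
    config = config, seed = seed, model_fs = model_fs,
    config_hash = config_hash(list(config, seed)),
    clinical = clinical, cmr = cmr, split = split, partition = part,
    normalization = stats, model = model, history = fit$history,
    predictions = data.frame(participant_id = ids, partition = part,
                             sex = sexes, true_ilvm = cmr$ilvm,
                             lvh_label = cmr$lvh_label,
                             predicted_ilvm = pred, lvh_probability = prob,
                             reference_threshold_label = ref_label,
                             stringsAsFactors = FALSE),
    recalibration = recal,
    cutoffs = tryCatch(cutoffs_from_recalibration(recal), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      c(male = NA_real_, female = NA_real_)
    }),
    report = report, benchmark = benchmark, explain = explain,
    elapsed_s = proc.time()[3] - t0
  ), class = "lvh_pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- result$config_hash
    write.csv(result$predictions,
              file.path(out_dir, sprintf("predictions_%s.csv", stamp)),
              row.names = FALSE)
    write.csv(fit$history$epochs,
              file.path(out_dir, sprintf("history_%s.csv", stamp)),
              row.names = FALSE)
    summary_json <- c(list(config_hash = stamp, seed = seed),
                      if (!is.null(report)) list(
                        n = report$n, n_positive = report$n_positive,
                        auroc = report$auroc, auroc_ci = report$auroc_ci,
                        sensitivity = report$metrics$sensitivity,
                        specificity = report$metrics$specificity,
                        f1 = report$metrics$f1,
                        mae = report$regression$mae, me = report$regression$me,
                        pearson_r = report$regression$pearson_r),
                      list(cutoffs = as.list(result$cutoffs)))
    jsonlite::write_json(summary_json,
                         file.path(out_dir, sprintf("evaluation_%s.json", stamp)),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Evaluate a fitted pipeline on a new synthetic cohort
#'
#' Applies a trained pipeline result (model, normalization statistics
#' and recalibration) to a freshly generated cohort, preprocessing it
#' identically: median-beat extraction, metadata assembly with the
#' *original training* normalization, prediction and recalibrated LVH
#' probabilities. This is the out-of-sample evaluation used to study
#' transfer between cohorts (and to verify that a model trained on a
#' signal-free cohort classifies at chance level).
#'
#' @param result an `lvh_pipeline_result`.
#' @param config a [synthetic_cohort_config()] describing the new cohort.
#' @return list with `predictions` (data.frame) and `auroc` (NA when the
#'   cohort holds a single class).
#' @export
evaluate_pipeline_on <- function(result, config) {
  stopifnot(inherits(result, "lvh_pipeline_result"),
            inherits(config, "cohort_config"))
  tables <- cohort_tables(config)
  n <- config$n_participants
  beats <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    pe <- participant_ecg(config, tables, i)
    mb <- tryCatch(extract_median_beat(pe$raw_ecg),
                   ecglvh_extraction_failure = function(e) NULL)
    if (!is.null(mb)) {
      beats[[i]] <- mb
      ok[i] <- TRUE
    }
  }
  clinical <- impute_missing(tables$clinical[ok, , drop = FALSE])
  cmr <- tables$cmr[ok, , drop = FALSE]
  beats <- beats[ok]
  rate <- vapply(beats, `[[`, numeric(1), "ventricular_rate_bpm")
  md <- metadata_features(clinical, ventricular_rate_bpm = rate)
  mdn <- normalize_features(md, result$normalization)
  wf <- simplify2array(lapply(beats, function(b) {
    if (!is.null(result$model_fs) && result$model_fs != b$sampling_rate_hz) {
      resample_beat(b$waveforms, b$sampling_rate_hz, result$model_fs)
    } else b$waveforms
  }))
  feats <- structure(list(ecg = wf, metadata = mdn, y = cmr$ilvm,
                          ids = cmr$participant_id), class = "fcn_features")
  pred <- predict(result$model, feats)
  prob <- predict(result$recalibration, pred, cmr$sex)
  auroc <- if (length(unique(cmr$lvh_label)) == 2) {
    auroc_empirical(prob, cmr$lvh_label)
  } else NA_real_
  list(predictions = data.frame(participant_id = cmr$participant_id,
                                sex = cmr$sex, true_ilvm = cmr$ilvm,
                                lvh_label = cmr$lvh_label,
                                predicted_ilvm = pred, lvh_probability = prob,
                                stringsAsFactors = FALSE),
       auroc = auroc)
}

#' @export
print.lvh_pipeline_result <- function(x, ...) {
  cat(sprintf("LVH pipeline result (%s, n = %d, seed %d, hash %s)\n",
              x$config$preset, nrow(x$cmr), x$seed, x$config_hash))
  cat(sprintf("  training: %d epochs (stop: %s)\n",
              nrow(x$history$epochs), x$history$stop_reason))
  cat(sprintf("  recalibrated cut-offs: male %.1f, female %.1f g/m^2\n",
              x$cutoffs[["male"]], x$cutoffs[["female"]]))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
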