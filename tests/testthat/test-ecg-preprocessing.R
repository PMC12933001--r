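test_that("the bandpass filter has the specified frequency response", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  # DC is rejected
  dc <- bandpass_filter(rep(2, length(t)), fs)
  expect_lt(max(abs(dc)), 1e-6 * 2)
  # 10 Hz passes within 5% (edges trimmed)
  s10 <- bandpass_filter(sin(2 * pi * 10 * t), fs)
  mid <- s10[(fs):(length(t) - fs)]
  expect_lt(abs(max(mid) - 1), 0.05)
  # 0.2 Hz is strongly attenuated
  s02 <- bandpass_filter(sin(2 * pi * 0.2 * t), fs)
  expect_lt(max(abs(s02[(2 * fs):(length(t) - 2 * fs)])), 0.1)
  # linearity
  x <- rnorm(2000)
  expect_equal(bandpass_filter(3.7 * x, fs), 3.7 * bandpass_filter(x, fs),
               tolerance = 1e-9)
  # validation
  expect_error(bandpass_filter(rnorm(100), fs = 80), "twice")
  expect_error(bandpass_filter(rnorm(10), fs), "too short")
})

test_that("R-peak detection matches simulator ground truth and its symmetries", {
  cfg <- quiet_config()
  tpl <- make_median_template(60, "male", 60, cfg)
  ecg <- make_raw_ecg(tpl, 60, cfg, seed = 4)
  p <- detect_r_peaks(ecg)
  expect_equal(length(p), ecg$meta$n_beats)
  expect_true(all(abs(p - ecg$meta$true_r_samples) <= 5))  # within 10 ms @ 500 Hz
  # globally inverted signal gives identical peaks
  inv <- ecg
  inv$samples <- -inv$samples
  expect_identical(detect_r_peaks(inv), p)
  # flat signal: empty with a warning
  flat <- ecg
  flat$samples[] <- 0
  expect_warning(p0 <- detect_r_peaks(flat), "no R peaks")
  expect_length(p0, 0)
  # noisy detection still within 10 ms
  ecgn <- make_raw_ecg(tpl, 60, quiet_config(noise_sd = 0.05, wander = 0.05,
                                             rr_jitter_ms = 25), seed = 8)
  pn <- detect_r_peaks(ecgn)
  hits <- vapply(pn, function(q) min(abs(q - ecgn$meta$true_r_samples)), numeric(1))
  expect_true(all(hits <= 5))
})

test_that("median-beat extraction is exact for identical beats and robust to noise", {
  rec <- clean_recording()
  mb <- extract_median_beat(rec$ecg, lowpass = NULL)
  expect_lt(max(abs(mb$waveforms - rec$template)), 1e-9)
  expect_equal(mb$n_beats_retained, mb$n_beats_detected)
  # rate identity on a zero-jitter 60 bpm recording
  cfg <- quiet_config()
  tpl <- make_median_template(60, "male", 60, cfg)
  mb60 <- extract_median_beat(make_raw_ecg(tpl, 60, cfg, seed = 2))
  expect_lt(abs(mb60$mean_rr_ms - 1000), 2)
  expect_lt(abs(mb60$ventricular_rate_bpm - 60), 0.12)
  expect_equal(mb60$ventricular_rate_bpm, 60000 / mb60$mean_rr_ms, tolerance = 1e-12)
  # noisy + corrupted: high template correlation, all corrupted rejected
  cfg_n <- quiet_config(noise_sd = 0.05, corrupt = 0.2, rr_jitter_ms = 25,
                        wander = 0.05)
  ecgn <- make_raw_ecg(tpl, 60, cfg_n, seed = 13)
  mbn <- extract_median_beat(ecgn)
  cors <- vapply(colnames(tpl), function(l) cor(mbn$waveforms[, l], tpl[, l]),
                 numeric(1))
  expect_true(all(cors >= 0.98))
  expect_gte(mean(cors), 0.99)
  bad <- ecgn$meta$true_r_samples[ecgn$meta$corrupted_beats]
  for (b in bad) expect_true(all(abs(mbn$retained_peaks - b) > 50))
  # rejection monotonicity: higher thresholds never retain more beats
  ret <- vapply(c(0.5, 0.7, 0.9, 0.99),
                function(th) extract_median_beat(ecgn, corr_threshold = th)$n_beats_retained,
                integer(1))
  expect_true(all(diff(ret) <= 0))
  # hard failure when too few beats survive rejection
  short_cfg <- quiet_config(duration_s = 5.5, corrupt = 0.5)
  short <- make_raw_ecg(make_median_template(60, "male", 48, short_cfg), 48,
                        short_cfg, seed = 1)
  expect_error(extract_median_beat(short), class = "ecglvh_extraction_failure")
})

test_that("resampling harmonises sampling rates", {
  cfg <- quiet_config(sampling_rate_hz = 250)
  tpl <- make_median_template(60, "male", 60, cfg)
  ecg <- make_raw_ecg(tpl, 60, cfg, seed = 5)
  mb <- extract_median_beat(ecg)     # resampled to 500 Hz internally
  expect_equal(mb$sampling_rate_hz, 500)
  expect_equal(nrow(mb$waveforms), 600)
  expect_lt(abs(mb$ventricular_rate_bpm - 60), 1)
})

test_that("min-max normalization is fitted on training data and invertible", {
  prof <- toy_profiles(8)
  md <- metadata_features(prof)
  expect_equal(ncol(md), 15)
  expect_identical(names(md), as.character(metadata_manifest()))
  stats <- fit_normalization(md)
  nm <- normalize_features(md, stats)
  cont <- attr(metadata_manifest(), "continuous")
  expect_true(all(nm[, cont] >= 0 & nm[, cont] <= 1))
  # endpoints and midpoint
  toy <- md[1:3, ]
  toy$age <- c(40, 60, 80)
  st <- fit_normalization(toy)
  expect_equal(unname(normalize_features(toy, st)[, "age"]), c(0, 0.5, 1))
  # out-of-range values extrapolate without clipping
  toy2 <- toy[1, ]; toy2$age <- 90
  expect_equal(unname(normalize_features(toy2, st)[1, "age"]), 1.25)
  # round trip
  expect_equal(denormalize_features(nm, stats)[, cont],
               as.matrix(md[, cont]), tolerance = 1e-9)
  # degenerate feature is an error naming the feature
  degen <- md; degen$bmi <- 25
  expect_error(fit_normalization(degen), "bmi")
})

test_that("smoking is one-hot encoded in never/previous/current order", {
  prof <- toy_profiles(3)
  prof$smoking <- c("never", "previous", "current")
  md <- metadata_features(prof)
  oh <- as.matrix(md[, c("smoking_never", "smoking_previous", "smoking_current")])
  expect_equal(unname(oh), rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  prof$smoking[1] <- "vaping"
  expect_error(metadata_features(prof), "smoking")
})

test_that("feature vectors carry the raw waveform and normalized metadata", {
  rec <- clean_recording()
  mb <- extract_median_beat(rec$ecg)
  prof <- toy_profiles(1)
  stats <- fit_normalization(metadata_features(toy_profiles(8)))
  fv <- build_feature_vector(mb, prof, stats, model_fs = NULL)
  expect_length(fv$metadata, 15)
  expect_identical(fv$ecg, mb$waveforms)   # no waveform normalization
  # all-zero waveform passes through unchanged
  mb0 <- mb; mb0$waveforms[] <- 0
  expect_true(all(build_feature_vector(mb0, prof, stats, model_fs = NULL)$ecg == 0))
  # decimation changes only the time axis
  fv100 <- build_feature_vector(mb, prof, stats, model_fs = 100)
  expect_equal(nrow(fv100$ecg), 120)
  expect_identical(fv100$metadata, fv$metadata)
})

test_that("imputation fills continuous with medians and categoricals with modes", {
  df <- data.frame(sbp = c(120, 130, NA, 140), flag = c(1, 1, 0, NA),
                   smoke = c("never", NA, "never", "current"),
                   stringsAsFactors = FALSE)
  out <- impute_missing(df)
  expect_equal(out$sbp[3], 130)
  expect_equal(out$flag[4], 1)
  expect_equal(out$smoke[2], "never")
  clean <- data.frame(a = 1:3)
  expect_identical(impute_missing(clean), clean)
  allna <- data.frame(x = c(NA_real_, NA_real_))
  expect_error(impute_missing(allna), "x")
})

test_that("text ECG files round-trip with unit conversion and lead aliases", {
  rec <- clean_recording()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ecg(rec$ecg, path)
  back <- read_ecg(path)
  expect_equal(back$sampling_rate_hz, rec$ecg$sampling_rate_hz)
  expect_equal(back$samples, rec$ecg$samples, tolerance = 1e-5,
               ignore_attr = TRUE)
  # microvolt source is divided by 1000; C-style and lowercase aliases map
  lines <- readLines(path)
  lines <- sub("# units: mV", "# units: uV", lines, fixed = TRUE)
  hdr_row <- grep("^I\t", lines)[1]
  lines[hdr_row] <- "lead I\tii\tC1\tv2\tV3\tV4\tC5\tV6"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, path2)
  uv <- read_ecg(path2)
  expect_identical(uv$lead_names, c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"))
  expect_equal(uv$samples[, "V1"], back$samples[, "V1"] / 1000,
               tolerance = 1e-12, ignore_attr = TRUE)
  # missing required leads are reported by name
  lines3 <- c(lines[seq_len(hdr_row - 1)], "I\tII",
              vapply(strsplit(lines[-seq_len(hdr_row)], "\t"),
                     function(v) paste(v[1:2], collapse = "\t"), character(1)))
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines3, path3)
  expect_error(read_ecg(path3), "V1")
})

test_that("cohorts written to disk round-trip through the manifest", {
  cohort <- generate_cohort(synthetic_cohort_config(n_participants = 3, seed = 6))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$cmr), 3)
  expect_named(back$ecgs, cohort$cmr$participant_id)
  expect_equal(back$ecgs[[2]]$samples,
               cohort$participants[[2]]$raw_ecg$samples,
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("median-beat archives round-trip through their manifest", {
  rec1 <- clean_recording(ilvm = 55, seed = 31)
  rec2 <- clean_recording(ilvm = 70, sex = "female", seed = 32)
  b1 <- extract_median_beat(rec1$ecg)
  b1$participant_id <- "A1"
  b2 <- extract_median_beat(rec2$ecg)
  b2$participant_id <- "A2"
  dir <- withr::local_tempdir()
  write_median_beats(list(b1, b2), dir)
  back <- read_median_beats(dir)
  expect_named(back, c("A1", "A2"))
  expect_equal(back$A1$waveforms, b1$waveforms, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(back$A2$ventricular_rate_bpm, b2$ventricular_rate_bpm,
               tolerance = 1e-9)
  expect_equal(back$A1$n_beats_retained, b1$n_beats_retained)
})
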