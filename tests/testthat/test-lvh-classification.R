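test_that("reference-threshold classification uses strict sex-specific cut-offs", {
  expect_false(classify_by_reference_threshold(70.0, "male"))
  expect_true(classify_by_reference_threshold(70.01, "male"))
  expect_true(classify_by_reference_threshold(56, "female"))
  expect_false(classify_by_reference_threshold(55, "female"))
  expect_error(classify_by_reference_threshold(NaN, "male"), "finite")
})

test_that("recalibration recovers generating cut-offs and implies closed-form thresholds", {
  set.seed(31)
  n <- 5000
  sex <- rep(0:1, length.out = n)
  pred <- runif(n, 30, 80)
  labels <- ifelse(sex == 1, pred > 58.9, pred > 46.9)
  # noiseless thresholded labels are completely separated: the fit warns
  # but the implied cut-offs converge to the generating boundaries
  fit <- suppressWarnings(fit_recalibration(pred, sex, labels))
  co <- cutoffs_from_recalibration(fit)
  expect_lt(abs(co[["male"]] - 58.9), 1)
  expect_lt(abs(co[["female"]] - 46.9), 1)
  # probability at the cut-off is exactly 0.5
  expect_equal(predict(fit, co[["male"]], 1), 0.5, tolerance = 1e-9)
  expect_equal(predict(fit, co[["female"]], 0), 0.5, tolerance = 1e-9)
  # sex-blind labels give a negligible sex shift
  lab2 <- pred > 52
  fit2 <- fit_recalibration(pred, sex, lab2)
  co2 <- cutoffs_from_recalibration(fit2)
  expect_lt(abs(co2[["male"]] - co2[["female"]]), 0.5)
  # single-class input cannot be recalibrated
  expect_error(fit_recalibration(pred, sex, rep(TRUE, n)), "both classes")
})

test_that("balanced class weights make cut-offs insensitive to prevalence", {
  set.seed(32)
  mk <- function(n_pos, n_neg) {
    # overlapping score distributions around a common boundary (~57)
    pred <- c(runif(n_pos, 52, 80), runif(n_neg, 30, 62))
    sex <- rbinom(n_pos + n_neg, 1, 0.5)
    lab <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    cutoffs_from_recalibration(fit_recalibration(pred, sex, lab))
  }
  rare <- mk(150, 2850)
  common <- mk(1500, 1500)
  expect_lt(abs(rare[["male"]] - common[["male"]]), 2)
  expect_lt(abs(rare[["female"]] - common[["female"]]), 2)
})

test_that("cut-off algebra matches hand-solved examples", {
  m <- structure(list(intercept = -10, beta_ilvm = 0.2, beta_sex = 0),
                 class = "lvh_recalibration")
  expect_equal(unname(cutoffs_from_recalibration(m)), c(50, 50))
  m2 <- structure(list(intercept = -10, beta_ilvm = 0.2, beta_sex = -2),
                  class = "lvh_recalibration")
  expect_equal(cutoffs_from_recalibration(m2)[["male"]], 60)
  expect_equal(cutoffs_from_recalibration(m2)[["female"]], 50)
  bad <- structure(list(intercept = 1, beta_ilvm = -0.1, beta_sex = 0),
                   class = "lvh_recalibration")
  expect_error(cutoffs_from_recalibration(bad), "monotone")
})

test_that("recalibration restores sensitivity lost to systematic underestimation", {
  # down-biased predictions: the fixed threshold misses cases, the
  # recalibrated rule recovers them
  set.seed(33)
  wins <- 0
  for (rep_i in 1:20) {
    n <- 1500
    sex <- rbinom(n, 1, 0.5)
    true_ilvm <- ifelse(sex == 1, rlnorm(n, log(48), 0.18), rlnorm(n, log(40), 0.15))
    labels <- true_ilvm > ifelse(sex == 1, 70, 55)
    if (sum(labels) < 5) next
    bias <- runif(1, -8, -2)
    pred <- true_ilvm + bias + rnorm(n, 0, 2)
    ref_sens <- mean(classify_by_reference_threshold(pred, sex)[labels])
    fitidx <- seq_len(n %/% 2)
    fit <- fit_recalibration(pred[fitidx], sex[fitidx], labels[fitidx])
    prob <- predict(fit, pred[-fitidx], sex[-fitidx])
    yj <- youden_operating_point(prob, labels[-fitidx])
    if (yj$sensitivity >= ref_sens) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("wave amplitudes are measured against a local baseline", {
  rec <- clean_recording(ilvm = 60)
  mb <- extract_median_beat(rec$ecg)
  v <- measure_wave_amplitudes(mb)
  tpl <- rec$template
  # compare against the known template extrema per lead
  for (ld in c("V1", "V3", "V5", "V6")) {
    expect_equal(v$r_mv[v$lead == ld], max(0, max(tpl[, ld])), tolerance = 0.02)
    expect_equal(v$s_mv[v$lead == ld], max(0, -min(tpl[, ld])), tolerance = 0.02)
  }
  # all-zero beat gives zero everywhere
  mb0 <- mb; mb0$waveforms[] <- 0
  v0 <- measure_wave_amplitudes(mb0)
  expect_true(all(v0$r_mv == 0 & v0$s_mv == 0))
  # lead I == lead II implies aVL == I/2 samplewise
  mb1 <- mb
  mb1$waveforms[, "II"] <- mb1$waveforms[, "I"]
  v1 <- measure_wave_amplitudes(mb1)
  half_i <- mb1$waveforms[, "I"] / 2
  expect_equal(v1$r_mv[v1$lead == "aVL"], max(0, max(half_i)), tolerance = 0.02)
})

test_that("voltage criteria implement the clinical formulas and boundaries", {
  mk <- function(s_v1, r_v5, r_v6, r_avl = 0, s_v3 = 0) {
    structure(data.frame(lead = c("V1", "V3", "V5", "V6", "aVL"),
                         r_mv = c(0, 0, r_v5, r_v6, r_avl),
                         s_mv = c(s_v1, s_v3, 0, 0, 0)),
              class = c("voltage_measurements", "data.frame"))
  }
  sl <- sokolow_lyon(mk(1.5, 1.8, 2.1))
  expect_equal(sl$index_mv, 3.6)
  expect_true(sl$positive)
  expect_false(sokolow_lyon(mk(1.0, 2.0, 1.9))$positive)
  expect_true(sokolow_lyon(mk(1.5, 2.0, 1.0))$positive)   # boundary 3.5 counts
  cv <- cornell_voltage(mk(0, 0, 0, r_avl = 1.2, s_v3 = 1.7), "male")
  expect_equal(cv$index_mv, 2.9)
  expect_true(cv$positive)
  expect_false(cornell_voltage(mk(0, 0, 0, r_avl = 1.1, s_v3 = 1.7), "male")$positive)
  expect_true(cornell_voltage(mk(0, 0, 0, r_avl = 0.4, s_v3 = 1.7), "female")$positive)
  # unit safety: doubling amplitudes doubles both indices exactly
  rec <- clean_recording(ilvm = 75)
  mb <- extract_median_beat(rec$ecg)
  mb2 <- mb; mb2$waveforms <- 2 * mb2$waveforms
  expect_equal(sokolow_lyon(measure_wave_amplitudes(mb2))$index_mv,
               2 * sokolow_lyon(measure_wave_amplitudes(mb))$index_mv,
               tolerance = 1e-9)
  expect_equal(cornell_voltage(measure_wave_amplitudes(mb2), 1)$index_mv,
               2 * cornell_voltage(measure_wave_amplitudes(mb), 1)$index_mv,
               tolerance = 1e-9)
})
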