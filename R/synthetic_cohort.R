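# Synthetic cohort generator: raw multi-beat ECGs whose morphology encodes a
# latent indexed LV mass, paired clinical covariates and CMR ground truth.
# The generator emulates the statistical structure of a population imaging
# cohort (sex-specific right-skewed iLVM, low LVH prevalence, covariate
# shifts between LVH and normal strata) so every downstream stage is
# testable without restricted data.

# Gaussian wave parameters of the synthetic beat (centres/widths in ms
# relative to the R peak, base amplitudes in mV before lead scaling).
beat_wave_table <- function() {
  data.frame(
    wave      = c("P", "Q", "R", "S", "T"),
    center_ms = c(-160, -25, 0, 30, 300),
    width_ms  = c(22, 6, 10, 8, 60),
    amp_mv    = c(0.12, -0.08, 1.00, -0.70, 0.32),
    stringsAsFactors = FALSE
  )
}

# Per-lead polarity/scale template: `rf` scales Q/R, `sf` scales S
# (V1-V2 net-negative QRS, V5-V6 net-positive), `pt` scales P/T.
lead_gain_table <- function() {
  data.frame(
    lead = canonical_leads(),
    rf = c(0.50, 0.90, 0.15, 0.30, 0.60, 1.00, 1.40, 1.20),
    sf = c(0.15, 0.15, 0.90, 0.80, 0.60, 0.35, 0.20, 0.15),
    pt = c(0.50, 0.90, 0.30, 0.50, 0.70, 0.90, 1.00, 0.90),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic ECG/CMR cohort generator
#'
#' Defaults emulate the baseline characteristics of a large population
#' imaging cohort: 51.8% female, sex-specific log-normal iLVM with means
#' 48 (male) / 40 (female) g/m^2 whose spread is solved so that the
#' fraction exceeding the sex-specific LVH thresholds equals
#' `lvh_prevalence_target` (1.5% by default), heart rate 59.3 +/- 10.8 bpm
#' in the LVH stratum vs 61.7 +/- 10.2 bpm otherwise, and covariate
#' location shifts between strata taken from the same table
#' (e.g. systolic BP 159 vs 142 mmHg). The `external` preset emulates a
#' second community cohort with a domain shift: 13 years younger, 5.8%
#' LVH prevalence, 250 Hz acquisition.
#'
#' ECG morphology is a sum of Gaussian waves (P, Q, R, S, T) per lead with
#' fixed polarity templates; R amplitude in the reference lead (V5) grows
#' by `qrs_amplitude_slope` mV per g/m^2 of iLVM above the sex reference
#' mean, S depth grows at half that rate, and QRS widths grow by
#' `qrs_width_slope` ms per g/m^2.
#'
#' @param n_participants cohort size (> 0).
#' @param preset `"ukb"` (default) or `"external"`.
#' @param sex_fraction_female proportion of females.
#' @param ilvm_mean named vector `c(male=, female=)`, g/m^2 (log-normal
#'   arithmetic means).
#' @param lvh_prevalence_target proportion exceeding the sex thresholds.
#' @param qrs_amplitude_slope mV per (g/m^2), reference lead V5.
#' @param qrs_width_slope ms per (g/m^2).
#' @param heart_rate list of `c(mean, sd)` per stratum (`lvh`, `normal`),
#'   beats/min.
#' @param covariate_distributions list of per-variable stratum
#'   distributions; see the default for the schema.
#' @param noise_sd additive Gaussian noise SD, mV.
#' @param baseline_wander_amplitude sinusoidal wander amplitude, mV.
#' @param baseline_wander_freq_hz wander frequency (< 1 Hz).
#' @param corrupt_beat_fraction fraction of beats replaced by distorted
#'   morphology (amplitude inversion + width doubling).
#' @param rr_jitter_ms SD of the R-R interval jitter, ms.
#' @param duration_s recording length, seconds.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param age_shift_years additive shift applied to the age distribution
#'   (used by the `external` preset).
#' @param seed integer seed; identical seed + config reproduces an
#'   identical cohort bit-for-bit.
#' @return object of class `cohort_config`.
#' @export
synthetic_cohort_config <- function(n_participants = 2000,
                                    preset = c("ukb", "external"),
                                    sex_fraction_female = 0.518,
                                    ilvm_mean = c(male = 48, female = 40),
                                    lvh_prevalence_target = NULL,
                                    qrs_amplitude_slope = 0.02,
                                    qrs_width_slope = 0.1,
                                    heart_rate = list(lvh = c(mean = 59.3, sd = 10.8),
                                                      normal = c(mean = 61.7, sd = 10.2)),
                                    covariate_distributions = NULL,
                                    noise_sd = 0.05,
                                    baseline_wander_amplitude = 0.05,
                                    baseline_wander_freq_hz = 0.25,
                                    corrupt_beat_fraction = 0.1,
                                    rr_jitter_ms = 25,
                                    duration_s = 15,
                                    sampling_rate_hz = NULL,
                                    age_shift_years = NULL,
                                    seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(lvh_prevalence_target)) {
    lvh_prevalence_target <- if (preset == "external") 0.058 else 0.015
  }
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- if (preset == "external") 250 else 500
  }
  if (is.null(age_shift_years)) {
    age_shift_years <- if (preset == "external") -13 else 0
  }
  if (is.null(covariate_distributions)) {
    covariate_distributions <- list(
      age        = list(normal = c(mean = 65, sd = 7.8),  lvh = c(mean = 64, sd = 7.7),
                        clamp = c(35, 90)),
      bmi        = list(normal = c(mean = 25.99, sd = 4.3), lvh = c(mean = 26.84, sd = 4.9),
                        clamp = c(15, 60)),
      sbp_raw    = list(normal = c(mean = 142, sd = 21.1), lvh = c(mean = 159, sd = 23),
                        clamp = c(70, 260)),
      dbp_raw    = list(normal = c(mean = 81, sd = 11.3), lvh = c(mean = 86, sd = 13.1),
                        clamp = c(40, 150)),
      total_chol_raw = list(normal = c(mean = 4.96, sd = 1.2), lvh = c(mean = 4.9, sd = 1.1),
                            clamp = c(1.5, 15)),
      non_hdl_raw = list(normal = c(mean = 3.5, sd = 1.2), lvh = c(mean = 3.5, sd = 1.1),
                         clamp = c(0.5, 12)),
      hba1c      = list(normal = c(mean = 38.5, sd = 6), lvh = c(mean = 39.5, sd = 6),
                        clamp = c(20, 120)),
      smoking    = list(normal = c(never = 0.610, previous = 0.335, current = 0.055),
                        lvh    = c(never = 0.584, previous = 0.332, current = 0.084)),
      alcohol_current    = list(normal = 0.947, lvh = 0.949),
      on_bp_medication   = list(normal = 0.20, lvh = 0.40),
      hypertension_dx    = list(normal = 0.30, lvh = 0.50),
      on_lipid_medication = list(normal = 0.20, lvh = 0.25)
    )
  }
  cfg <- list(
    n_participants = as.integer(n_participants), preset = preset,
    sex_fraction_female = sex_fraction_female, ilvm_mean = ilvm_mean,
    lvh_prevalence_target = lvh_prevalence_target,
    qrs_amplitude_slope = qrs_amplitude_slope, qrs_width_slope = qrs_width_slope,
    heart_rate = heart_rate, covariate_distributions = covariate_distributions,
    noise_sd = noise_sd, baseline_wander_amplitude = baseline_wander_amplitude,
    baseline_wander_freq_hz = baseline_wander_freq_hz,
    corrupt_beat_fraction = corrupt_beat_fraction, rr_jitter_ms = rr_jitter_ms,
    duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
    age_shift_years = age_shift_years, seed = as.integer(seed),
    waves = beat_wave_table(), lead_gains = lead_gain_table(),
    reference_lead = "V5"
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Zero-effect-size cohort configuration
#'
#' A diagnostic variant of [synthetic_cohort_config()] in which nothing
#' in the ECG or the covariates carries information about iLVM or LVH:
#' the QRS amplitude/width slopes are zero, both LVH strata share one
#' heart-rate distribution, and all covariate distributions are
#' identical across strata. A model trained on such a cohort should
#' classify LVH no better than chance; the elevated default prevalence
#' keeps the sampling error of a null AUROC small enough for that check
#' to be informative.
#'
#' @param n_participants cohort size.
#' @param lvh_prevalence_target LVH fraction (default 0.15; diagnostic
#'   use only).
#' @param seed integer seed.
#' @param ... further arguments passed to [synthetic_cohort_config()].
#' @return object of class `cohort_config`.
#' @export
null_cohort_config <- function(n_participants = 2000,
                               lvh_prevalence_target = 0.15, seed = 1L, ...) {
  base <- synthetic_cohort_config(n_participants = n_participants, seed = seed)
  cd <- base$covariate_distributions
  for (nm in names(cd)) cd[[nm]]$lvh <- cd[[nm]]$normal
  synthetic_cohort_config(
    n_participants = n_participants, seed = seed,
    lvh_prevalence_target = lvh_prevalence_target,
    qrs_amplitude_slope = 0, qrs_width_slope = 0,
    heart_rate = list(lvh = c(mean = 61.7, sd = 10.2),
                      normal = c(mean = 61.7, sd = 10.2)),
    covariate_distributions = cd, ...)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants <= 0) stop_invalid("n_participants must be > 0")
  props <- c(cfg$sex_fraction_female, cfg$lvh_prevalence_target,
             cfg$corrupt_beat_fraction)
  if (any(props < 0 | props > 1)) stop_invalid("proportions must lie in [0, 1]")
  if (cfg$sampling_rate_hz <= 0) stop_invalid("sampling_rate_hz must be > 0")
  if (cfg$noise_sd < 0 || cfg$baseline_wander_amplitude < 0 ||
      cfg$rr_jitter_ms < 0 || cfg$qrs_width_slope < 0) {
    stop_invalid("scales must be non-negative")
  }
  # prevalence feasibility check (errors if unreachable)
  lognormal_params(cfg$ilvm_mean[["male"]], lvh_thresholds()[["male"]],
                   cfg$lvh_prevalence_target)
  lognormal_params(cfg$ilvm_mean[["female"]], lvh_thresholds()[["female"]],
                   cfg$lvh_prevalence_target)
  invisible(cfg)
}

# Solve the log-normal sdlog so that P(X > threshold) == p for a
# distribution with arithmetic mean m: sdlog^2/2 - z*sdlog + log(thr/m) = 0
# with z = qnorm(1 - p); the smaller root is the realistic (less skewed)
# solution. Infeasible targets (no real root) raise a configuration error.
lognormal_params <- function(mean, threshold, p) {
  if (p <= 0 || p >= 0.5) stop_invalid("lvh_prevalence_target must be in (0, 0.5)")
  if (threshold <= mean) stop_invalid("iLVM mean must lie below the LVH threshold")
  z <- qnorm(1 - p)
  disc <- z^2 - 2 * log(threshold / mean)
  if (disc <= 0) {
    stop_invalid("infeasible lvh_prevalence_target %.4g for mean %.3g and threshold %.3g",
                 p, mean, threshold)
  }
  sdlog <- z - sqrt(disc)
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Noiseless per-lead beat template for a given iLVM
#'
#' Builds one beat per lead (I, II, V1-V6) over a 1.2 s window (R peak at
#' 0.4 s) as a sum of Gaussian waves. The R amplitude in the reference
#' lead (V5) increases by exactly `qrs_amplitude_slope` mV per g/m^2 of
#' iLVM above the sex-specific reference mean (other leads scale
#' proportionally to their gain), S depth increases at half that rate, and
#' Q/R/S widths by `qrs_width_slope` ms per g/m^2. The T-wave interval
#' shortens with heart rate (square-root rate correction). Deterministic
#' given its arguments.
#'
#' @param ilvm indexed LV mass, g/m^2 (> 0).
#' @param sex any encoding accepted by [as_sex()].
#' @param heart_rate beats per minute (> 0).
#' @param config a [synthetic_cohort_config()].
#' @return numeric matrix (L x 8, mV) with `lead` column names and
#'   attributes `sampling_rate_hz` and `r_index` (1-based R sample).
#' @export
make_median_template <- function(ilvm, sex, heart_rate, config) {
  if (!is.finite(ilvm) || ilvm <= 0) stop_invalid("ilvm must be positive")
  if (!is.finite(heart_rate) || heart_rate <= 0) stop_invalid("heart_rate must be positive")
  sex <- as_sex(sex)
  fs <- config$sampling_rate_hz
  L <- round(1.2 * fs)
  r_index <- round(0.4 * fs)              # 0-based R sample within the window
  t_ms <- (seq_len(L) - 1 - r_index) / fs * 1000
  ref_mean <- if (sex == 1L) config$ilvm_mean[["male"]] else config$ilvm_mean[["female"]]
  delta_amp <- config$qrs_amplitude_slope * (ilvm - ref_mean)
  delta_width <- config$qrs_width_slope * (ilvm - ref_mean)

  waves <- config$waves
  gains <- config$lead_gains
  rr_s <- 60 / heart_rate
  out <- matrix(0, nrow = L, ncol = nrow(gains),
                dimnames = list(NULL, gains$lead))
  max_rf <- max(gains$rf)
  max_sf <- max(gains$sf)
  for (li in seq_len(nrow(gains))) {
    g <- gains[li, ]
    y <- numeric(L)
    for (wi in seq_len(nrow(waves))) {
      w <- waves[wi, ]
      center <- w$center_ms
      width <- w$width_ms
      amp <- w$amp_mv
      if (w$wave %in% c("Q", "R", "S")) {
        width <- max(2, width + delta_width)
        if (w$wave == "R") amp <- g$rf * amp + (g$rf / max_rf) * delta_amp
        else if (w$wave == "S") amp <- g$sf * amp - (g$sf / max_sf) * delta_amp / 2
        else amp <- g$rf * amp
      } else {
        if (w$wave == "T") center <- center * sqrt(rr_s)
        amp <- g$pt * amp
      }
      y <- y + amp * exp(-0.5 * ((t_ms - center) / width)^2)
    }
    out[, li] <- y
  }
  attr(out, "sampling_rate_hz") <- fs
  attr(out, "r_index") <- r_index + 1L    # 1-based for R users
  out
}

# Amplitude-inverted variant of a beat template with the QRS width
# doubled, used for the corrupted beats that the alignment stage must
# reject. The time stretch is local to the QRS (half-speed within
# +/- 120 ms of R, ramping back to the identity map by +/- 360 ms;
# continuous and monotone), so the distorted beat stays within its own
# window and does not leak into the neighbouring beats' baseline
# regions.
corrupt_template <- function(template) {
  L <- nrow(template)
  fs <- attr(template, "sampling_rate_hz")
  r1 <- attr(template, "r_index")         # 1-based
  z1 <- round(0.12 * fs)                  # stretched zone: R +/- 120 ms
  z2 <- round(0.36 * fs)                  # identity resumes beyond +/- 360 ms
  d <- seq_len(L) - r1
  ad <- abs(d)
  ramp <- z1 / 2 + (ad - z1) * (z2 - z1 / 2) / (z2 - z1)
  src <- r1 + sign(d) * ifelse(ad <= z1, ad / 2, ifelse(ad <= z2, ramp, ad))
  out <- template
  for (j in seq_len(ncol(template))) {
    out[, j] <- -approx(seq_len(L), template[, j], xout = src, rule = 2)$y
  }
  out
}

#' Synthesize a raw multi-beat ECG recording from a beat template
#'
#' Concatenates beats at R-R intervals drawn around `60000 / heart_rate`
#' ms with Gaussian jitter, adds white noise and a slow sinusoidal
#' baseline wander, and replaces a configured fraction of beats with a
#' distorted morphology (inverted amplitude, doubled width). True R-peak
#' times and the indices of corrupted beats are recorded as metadata for
#' downstream ground-truth tests.
#'
#' @param template beat template from [make_median_template()].
#' @param heart_rate beats per minute.
#' @param config a [synthetic_cohort_config()].
#' @param seed integer seed for the recording-level randomness.
#' @param participant_id identifier stored on the recording.
#' @return object of class `raw_ecg`: list with `samples` (n x 8 matrix,
#'   mV), `lead_names`, `sampling_rate_hz`, `duration_s`,
#'   `participant_id`, and `meta` (true R times in seconds, 1-based true
#'   R sample indices, corrupted beat indices).
#' @export
make_raw_ecg <- function(template, heart_rate, config, seed = config$seed,
                         participant_id = "synthetic") {
  fs <- config$sampling_rate_hz
  dur <- config$duration_s
  L <- nrow(template)
  r1 <- attr(template, "r_index")
  rr_s <- 60 / heart_rate
  with_seed(seed, {
    r_times <- c()
    t <- 0.45
    while (t + 0.8 <= dur) {
      r_times <- c(r_times, t)
      t <- t + rr_s + rnorm(1, 0, config$rr_jitter_ms / 1000)
    }
    n_beats <- length(r_times)
    if (n_beats < 3) {
      stop_invalid("duration_s too short: only %d beat(s) fit the recording", n_beats)
    }
    n_corrupt <- round(config$corrupt_beat_fraction * n_beats)
    corrupted <- if (n_corrupt > 0) sort(sample.int(n_beats, n_corrupt)) else integer(0)
    bad <- if (n_corrupt > 0) corrupt_template(template) else NULL

    n <- round(dur * fs)
    x <- matrix(0, nrow = n, ncol = ncol(template),
                dimnames = list(NULL, colnames(template)))
    r_samples <- integer(n_beats)
    for (b in seq_len(n_beats)) {
      r_smp <- round(r_times[b] * fs)     # 0-based sample of the R peak
      r_samples[b] <- r_smp + 1L
      rows <- (r_smp - (r1 - 1)) + seq_len(L)   # 1-based target rows
      keep <- rows >= 1 & rows <= n
      tpl <- if (b %in% corrupted) bad else template
      x[rows[keep], ] <- x[rows[keep], ] + tpl[keep, ]
    }
    if (config$noise_sd > 0) {
      x <- x + matrix(rnorm(length(x), 0, config$noise_sd), nrow = n)
    }
    if (config$baseline_wander_amplitude > 0) {
      tt <- (seq_len(n) - 1) / fs
      for (j in seq_len(ncol(x))) {
        x[, j] <- x[, j] + config$baseline_wander_amplitude *
          sin(2 * pi * config$baseline_wander_freq_hz * tt + runif(1, 0, 2 * pi))
      }
    }
    structure(list(participant_id = participant_id,
                   lead_names = colnames(template), samples = x,
                   sampling_rate_hz = fs, duration_s = dur,
                   meta = list(true_r_times_s = r_times,
                               true_r_samples = r_samples,
                               corrupted_beats = corrupted,
                               n_beats = n_beats)),
              class = "raw_ecg")
  })
}

# Vectorised covariate sampler over participants (internal).
sample_profiles <- function(lvh_status, sex, config, seed) {
  n <- length(lvh_status)
  cd <- config$covariate_distributions
  draw_cont <- function(spec) {
    mu <- ifelse(lvh_status, spec$lvh[["mean"]], spec$normal[["mean"]])
    sdv <- ifelse(lvh_status, spec$lvh[["sd"]], spec$normal[["sd"]])
    pmin(pmax(rnorm(n, mu, sdv), spec$clamp[1]), spec$clamp[2])
  }
  draw_flag <- function(spec) {
    p <- ifelse(lvh_status, spec$lvh, spec$normal)
    runif(n) < p
  }
  with_seed(seed, {
    age <- draw_cont(cd$age) + config$age_shift_years
    bmi <- draw_cont(cd$bmi)
    sbp <- draw_cont(cd$sbp_raw)
    dbp <- draw_cont(cd$dbp_raw)
    chol <- draw_cont(cd$total_chol_raw)
    non_hdl <- pmin(draw_cont(cd$non_hdl_raw), chol - 0.5)
    hba1c <- draw_cont(cd$hba1c)
    u <- runif(n)
    p_nev <- ifelse(lvh_status, cd$smoking$lvh[["never"]], cd$smoking$normal[["never"]])
    p_prev <- ifelse(lvh_status, cd$smoking$lvh[["previous"]], cd$smoking$normal[["previous"]])
    smoking <- ifelse(u < p_nev, "never", ifelse(u < p_nev + p_prev, "previous", "current"))
    alcohol <- ifelse(draw_flag(cd$alcohol_current), "current", "never")
    on_bp_med <- draw_flag(cd$on_bp_medication)
    htn_dx <- draw_flag(cd$hypertension_dx)
    on_lipid_med <- draw_flag(cd$on_lipid_medication)
    data.frame(age = age, sex = as.integer(sex), bmi = bmi,
               sbp_raw = sbp, dbp_raw = dbp, on_bp_medication = on_bp_med,
               hypertension_dx = htn_dx, total_chol_raw = chol,
               non_hdl_raw = non_hdl, on_lipid_medication = on_lipid_med,
               hba1c = hba1c, smoking = smoking, alcohol = alcohol,
               stringsAsFactors = FALSE)
  })
}

#' Sample a clinical covariate profile for one stratum
#'
#' Draws age, BMI, blood pressure, cholesterol, HbA1c, smoking, alcohol
#' and medication flags from the stratum-specific distributions in the
#' config, with physiological range clamps. Adjusted values and condition
#' flags are then derived with [adjust_bp()], [adjust_cholesterol()] and
#' [derive_conditions()].
#'
#' @param lvh_status logical (scalar or vector): sample from the LVH or
#'   the normal stratum.
#' @param sex sex value(s), any encoding accepted by [as_sex()].
#' @param config a [synthetic_cohort_config()].
#' @param seed integer seed.
#' @param n number of profiles when `lvh_status`/`sex` are scalars.
#' @return data.frame of raw, adjusted and derived covariates.
#' @export
sample_clinical_profile <- function(lvh_status, sex, config, seed = config$seed,
                                    n = NULL) {
  if (!is.null(n)) {
    lvh_status <- rep_len(lvh_status, n)
    sex <- rep_len(as_sex(sex), n)
  } else {
    sex <- as_sex(sex)
    n <- length(lvh_status)
  }
  prof <- sample_profiles(as.logical(lvh_status), sex, config, seed)
  prof <- cbind(prof, adjust_bp(prof$sbp_raw, prof$dbp_raw, prof$on_bp_medication))
  prof <- cbind(prof, adjust_cholesterol(prof$total_chol_raw, prof$non_hdl_raw,
                                         prof$on_lipid_medication))
  derive_conditions(prof)
}

# Draws everything except the waveforms: sex, iLVM, labels, heart rate,
# covariates and anthropometrics, as aligned data.frames (internal; the
# per-participant ECG seeds are derived from the config seed so cohorts
# can also be materialised participant-by-participant).
cohort_tables <- function(config) {
  n <- config$n_participants
  thr <- lvh_thresholds()
  base_seed <- config$seed
  with_seed(derive_seed(base_seed, 0L), {
    sex <- as.integer(runif(n) >= config$sex_fraction_female)  # 1 = male
    pm <- lognormal_params(config$ilvm_mean[["male"]], thr[["male"]],
                           config$lvh_prevalence_target)
    pf <- lognormal_params(config$ilvm_mean[["female"]], thr[["female"]],
                           config$lvh_prevalence_target)
    ilvm <- ifelse(sex == 1L,
                   rlnorm(n, pm$meanlog, pm$sdlog),
                   rlnorm(n, pf$meanlog, pf$sdlog))
    lvh <- ilvm > ifelse(sex == 1L, thr[["male"]], thr[["female"]])
    hr_mu <- ifelse(lvh, config$heart_rate$lvh[["mean"]], config$heart_rate$normal[["mean"]])
    hr_sd <- ifelse(lvh, config$heart_rate$lvh[["sd"]], config$heart_rate$normal[["sd"]])
    heart_rate <- pmin(pmax(rnorm(n, hr_mu, hr_sd), 40), 120)
    height <- ifelse(sex == 1L,
                     pmin(pmax(rnorm(n, 175, 7), 150), 205),
                     pmin(pmax(rnorm(n, 162, 6), 140), 195))
  })
  clinical <- sample_clinical_profile(lvh, sex, config,
                                      seed = derive_seed(base_seed, 1L))
  weight <- clinical$bmi * (height / 100)^2
  cmr0 <- index_and_label(ilvm * mosteller_bsa(height, weight), height, weight, sex)
  ids <- sprintf("P%05d", seq_len(n))
  clinical <- cbind(participant_id = ids, clinical, stringsAsFactors = FALSE)
  cmr <- data.frame(participant_id = ids, sex = sex,
                    lvm_g = ilvm * cmr0$bsa_m2, height_cm = height,
                    weight_kg = weight, bsa_m2 = cmr0$bsa_m2,
                    ilvm = ilvm, lvh_label = lvh,
                    heart_rate_bpm = heart_rate,
                    stringsAsFactors = FALSE)
  list(clinical = clinical, cmr = cmr)
}

# Materialise one participant's noiseless template and raw recording
# (internal; deterministic for a given config + row index).
participant_ecg <- function(config, tables, i) {
  cmr <- tables$cmr[i, ]
  template <- make_median_template(cmr$ilvm, cmr$sex, cmr$heart_rate_bpm, config)
  raw <- make_raw_ecg(template, cmr$heart_rate_bpm, config,
                      seed = derive_seed(config$seed, 1000L + i),
                      participant_id = cmr$participant_id)
  list(template = template, raw_ecg = raw)
}

#' Generate a complete synthetic cohort
#'
#' Draws sex, sex-specific log-normal iLVM calibrated so the fraction
#' exceeding the LVH thresholds matches the configured prevalence target,
#' clinical covariates shifted by LVH stratum, anthropometrics (LVM =
#' iLVM x BSA), and per-participant raw ECGs whose QRS morphology encodes
#' the latent iLVM. Deterministic under a fixed seed.
#'
#' @param config a [synthetic_cohort_config()].
#' @param keep_raw logical; set `FALSE` to omit raw waveforms (tables and
#'   templates only), useful for large cohorts.
#' @return object of class `synthetic_cohort`: list with `config`,
#'   `clinical` (data.frame), `cmr` (data.frame) and `participants`
#'   (list of `participant_id`, `true_template`, `raw_ecg`).
#' @export
generate_cohort <- function(config, keep_raw = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  tables <- cohort_tables(config)
  participants <- lapply(seq_len(config$n_participants), function(i) {
    pe <- participant_ecg(config, tables, i)
    list(participant_id = tables$cmr$participant_id[i],
         true_template = pe$template,
         raw_ecg = if (keep_raw) pe$raw_ecg else NULL)
  })
  structure(list(config = config, clinical = tables$clinical,
                 cmr = tables$cmr, participants = participants),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort (%s preset): %d participants, %.1f%% LVH\n",
              x$config$preset, nrow(x$cmr), 100 * mean(x$cmr$lvh_label)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one columnar text ECG file per participant (see [write_ecg()]),
#' the clinical and CMR tables as CSV, and a JSON manifest mapping
#' participant ids to files.
#'
#' @param cohort a `synthetic_cohort` (generated with `keep_raw = TRUE`).
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest as a data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(cohort$participants, function(p) {
    if (is.null(p$raw_ecg)) stop_invalid("cohort was generated with keep_raw = FALSE")
    f <- file.path(dir, paste0(p$participant_id, ".ecg.tsv"))
    write_ecg(p$raw_ecg, f)
    basename(f)
  }, character(1))
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(cohort$cmr, file.path(dir, "cmr.csv"), row.names = FALSE)
  manifest <- data.frame(participant_id = cohort$cmr$participant_id,
                         ecg_file = files, stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), dataframe = "rows")
  invisible(manifest)
}
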