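# Median-beat extraction from raw multi-lead ECG and assembly of
# normalized model inputs: bandpass filtering, R-peak detection on the
# leads' first principal component, cross-correlation beat alignment with
# rejection of uncorrelated beats, pointwise averaging, min-max feature
# normalization and mode/median imputation.

# Zero-phase IIR filtering: the filter's squared magnitude response is
# applied in the frequency domain (identical in effect to forward-
# backward filtering) on an odd-reflection padded signal, which keeps
# the operation exactly linear and free of edge transients.
zero_phase_filter <- function(x, filt, pad) {
  n <- length(x)
  pad <- min(n - 1L, pad)
  xp <- c(2 * x[1] - x[(pad + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  m <- length(xp)
  w <- 2 * pi * (seq_len(m) - 1) / m
  E <- exp(-1i * w)
  B <- 0; for (k in seq_along(filt$b)) B <- B + filt$b[k] * E^(k - 1)
  A <- 0; for (k in seq_along(filt$a)) A <- A + filt$a[k] * E^(k - 1)
  H2 <- Mod(B / A)^2
  y <- Re(stats::fft(stats::fft(xp) * H2, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Order-4 Butterworth bandpass applied with zero phase (the squared
#' magnitude response, as in forward-backward filtering), preserving QRS
#' timing. Output length equals input length.
#'
#' @param x numeric vector (one lead).
#' @param fs sampling rate, Hz; must exceed `2 * high`.
#' @param low,high passband edges, Hz (defaults 1 and 45).
#' @param order filter order (default 4).
#' @return filtered numeric vector, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 1, high = 45, order = 4) {
  if (fs <= 2 * high) stop_invalid("fs must exceed twice the upper passband edge")
  if (length(x) <= 3 * (2 * order + 1)) {
    stop_invalid("signal too short (%d samples) for an order-%d zero-phase filter",
                 length(x), order)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  zero_phase_filter(x, bf, pad = round(fs / low))
}

filter_leads <- function(ecg) {
  apply(ecg$samples, 2, bandpass_filter, fs = ecg$sampling_rate_hz)
}

#' Linearly resample a raw ECG to a target rate
#'
#' @param ecg a `raw_ecg` object.
#' @param target_fs target sampling rate, Hz.
#' @return a `raw_ecg` at `target_fs` (true R-peak sample metadata, when
#'   present, is recomputed from the recorded R times).
#' @export
resample_ecg <- function(ecg, target_fs) {
  if (ecg$sampling_rate_hz == target_fs) return(ecg)
  n_old <- nrow(ecg$samples)
  t_old <- (seq_len(n_old) - 1) / ecg$sampling_rate_hz
  n_new <- round(ecg$duration_s * target_fs)
  t_new <- (seq_len(n_new) - 1) / target_fs
  y <- vapply(seq_len(ncol(ecg$samples)), function(j) {
    approx(t_old, ecg$samples[, j], xout = t_new, rule = 2)$y
  }, numeric(n_new))
  colnames(y) <- colnames(ecg$samples)
  ecg$samples <- y
  ecg$sampling_rate_hz <- target_fs
  if (!is.null(ecg$meta$true_r_times_s)) {
    ecg$meta$true_r_samples <- round(ecg$meta$true_r_times_s * target_fs) + 1L
  }
  ecg
}

#' Detect R peaks on the first principal component of the filtered leads
#'
#' Bandpass-filters all leads and computes their first principal
#' component. Peak picking runs on a QRS-emphasizing slope signal (the
#' rectified, 10 ms-smoothed first difference of the component, which
#' suppresses the slow T wave) with an adaptive threshold of 0.5 x the
#' rolling maximum over 3 s segments, a 250 ms refractory period
#' (keeping the larger peak), and final refinement of each peak to the
#' local maximum of the rectified component within +/- 50 ms. Detection
#' is invariant to a global sign flip of the recording.
#'
#' @param ecg a `raw_ecg` object.
#' @param refractory_ms minimum distance between peaks, ms.
#' @return strictly increasing 1-based sample indices of the detected R
#'   peaks; empty (with a warning) when no peak exceeds the threshold.
#' @export
detect_r_peaks <- function(ecg, refractory_ms = 250) {
  fs <- ecg$sampling_rate_hz
  if (nrow(ecg$samples) < 3 * fs) stop_invalid("need at least 3 s of signal")
  pc1 <- principal_component(ecg)
  peaks_from_pc(pc1, fs, refractory_ms)
}

# First principal component of the bandpass-filtered leads (internal).
principal_component <- function(ecg) {
  xf <- filter_leads(ecg)
  prcomp(xf, center = TRUE, scale. = FALSE)$x[, 1]
}

peaks_from_pc <- function(pc1, fs, refractory_ms = 250) {
  a <- abs(pc1)
  n <- length(a)
  k <- max(3L, round(0.01 * fs))
  # centred moving average of the first difference via cumulative sums
  d <- c(0, diff(pc1))
  cs <- cumsum(c(0, d))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 0L)
  hi <- pmin(seq_len(n) + (k - half - 1L), n)
  s <- abs((cs[hi + 1L] - cs[lo + 1L]) / pmax(hi - lo, 1L))
  seg <- ceiling(seq_len(n) / (3 * fs))
  seg_max <- vapply(split(s, seg), max, numeric(1))
  thr <- pmax(0.5 * seg_max[seg], 0.2 * max(s))
  cand <- which(s > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[s[cand] > s[cand - 1] & s[cand] >= s[cand + 1]]
  if (!length(cand)) {
    warning("no R peaks detected", call. = FALSE)
    return(integer(0))
  }
  refr <- refractory_ms / 1000 * fs
  half <- round(0.05 * fs)
  refine <- function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    lo + which.max(a[lo:hi]) - 1L
  }
  kept <- integer(0)
  for (i in cand[order(s[cand], decreasing = TRUE)]) {
    r <- refine(i)
    if (!length(kept) || all(abs(kept - r) >= refr)) kept <- c(kept, r)
  }
  sort(unique(kept))
}

# Baseline-wander removal by natural-spline interpolation through
# per-beat isoelectric anchors (the 100 ms at the start of each beat
# window, well before the P wave). Falls back to linear interpolation
# when fewer than four beats are available.
remove_wander <- function(x, peaks, pre, fs) {
  k <- max(1L, round(0.1 * fs))
  starts <- peaks - pre
  centers <- starts + (k - 1) / 2
  for (j in seq_len(ncol(x))) {
    ys <- vapply(starts, function(s) mean(x[s:(s + k - 1L), j]), numeric(1))
    base <- if (length(starts) >= 4) {
      spline(centers, ys, xout = seq_len(nrow(x)), method = "natural")$y
    } else {
      approx(centers, ys, xout = seq_len(nrow(x)), rule = 2)$y
    }
    x[, j] <- x[, j] - base
  }
  x
}

# Per-beat linear baseline estimated from the mean of the first and last
# `anchor_ms` of the window (both lie in isoelectric regions of a beat).
subtract_baseline <- function(beat, fs, anchor_ms = 100) {
  L <- nrow(beat)
  k <- max(1L, round(anchor_ms / 1000 * fs))
  i1 <- seq_len(k)
  i2 <- (L - k + 1):L
  m1 <- colMeans(beat[i1, , drop = FALSE])
  m2 <- colMeans(beat[i2, , drop = FALSE])
  c1 <- mean(i1); c2 <- mean(i2)
  slope <- (m2 - m1) / (c2 - c1)
  base <- outer(seq_len(L) - c1, slope) + rep(m1, each = L)
  beat - base
}

#' Extract the signal-averaged median beat from a raw ECG
#'
#' Windows each detected beat around its R peak (400 ms pre-R, 800 ms
#' post-R), removes baseline wander by spline interpolation through
#' per-beat isoelectric anchors plus a per-beat linear baseline anchored
#' on the window edges, aligns each beat to a robust template (the
#' pointwise median across beats of the leads' first principal
#' component) by the lag maximizing normalized cross-correlation
#' (search +/- 50 ms; one lag per beat, applied to all leads), rejects
#' beats whose maximal correlation falls below `corr_threshold`, and
#' averages the retained aligned beats pointwise per lead. The mean R-R
#' interval over adjacent retained beats gives the ventricular rate.
#'
#' Recordings not sampled at `resample_to` Hz are linearly resampled
#' first so median beats are rate-harmonised across sources.
#'
#' @param ecg a `raw_ecg` object.
#' @param pre_ms,post_ms window extent around the R peak (total 1.2 s).
#' @param corr_threshold normalized cross-correlation rejection threshold.
#' @param max_lag_ms alignment search half-width, ms.
#' @param resample_to processing rate, Hz (default 500; `NULL` keeps the
#'   native rate).
#' @param lowpass cut-off (Hz) of the zero-phase low-pass applied to the
#'   signal that is windowed and averaged (default 45, matching the upper
#'   passband edge; `NULL` averages the raw samples). The full 1-45 Hz
#'   bandpass is used only on the detection path: its high-pass component
#'   visibly distorts the T wave, and slow drift is instead removed by
#'   the per-beat linear baseline.
#' @return object of class `median_beat`: `waveforms` (L x 8 matrix, mV),
#'   `sampling_rate_hz`, `r_index` (1-based R sample in the window),
#'   `mean_rr_ms`, `ventricular_rate_bpm`, `n_beats_detected`,
#'   `n_beats_retained`, `retained_peaks` (aligned 1-based R samples),
#'   `rejected_peaks`.
#' @export
extract_median_beat <- function(ecg, pre_ms = 400, post_ms = 800,
                                corr_threshold = 0.8, max_lag_ms = 50,
                                resample_to = 500, lowpass = 45) {
  if (!is.null(resample_to)) ecg <- resample_ecg(ecg, resample_to)
  fs <- ecg$sampling_rate_hz
  pre <- round(pre_ms / 1000 * fs)
  post <- round(post_ms / 1000 * fs)
  L <- pre + post
  max_lag <- round(max_lag_ms / 1000 * fs)
  n <- nrow(ecg$samples)

  avg_src <- if (is.null(lowpass)) ecg$samples else {
    lp <- signal::butter(4, lowpass / (fs / 2), type = "low")
    apply(ecg$samples, 2, zero_phase_filter, filt = lp,
          pad = round(3 * fs / lowpass))
  }
  # detection/alignment signal: first principal component of the
  # low-passed leads, bandpassed once to strip residual wander
  pc1 <- bandpass_filter(prcomp(avg_src, center = TRUE, scale. = FALSE)$x[, 1], fs)
  peaks <- peaks_from_pc(pc1, fs)
  window_of <- function(p) (p - pre):(p + post - 1L)   # R lands at index pre + 1
  full <- peaks[(peaks - pre - max_lag) >= 1 & (peaks + post + max_lag) <= n]
  if (length(full) < 3) {
    stop(structure(class = c("ecglvh_extraction_failure", "error", "condition"),
                   list(message = sprintf(
                     "median-beat extraction failed for %s: %d usable beat(s), need >= 3",
                     ecg$participant_id %||% "<unknown>", length(full)),
                     call = NULL, participant_id = ecg$participant_id)))
  }

  avg_src <- remove_wander(avg_src, full, pre, fs)

  # Alignment and rejection run on the high-SNR principal component,
  # over a core window (-250..+450 ms) that excludes neighbouring beats
  # at short cycle lengths; the selected lag is then applied to all
  # leads simultaneously.
  core_pre <- round(0.25 * fs)
  core_post <- round(0.45 * fs)
  core_of <- function(p) (p - core_pre):(p + core_post - 1L)
  Lc <- core_pre + core_post
  pc_beats <- vapply(full, function(p) pc1[core_of(p)], numeric(Lc))
  pc_tpl <- apply(pc_beats, 1, median)
  lags <- -max_lag:max_lag
  best_lag <- numeric(length(full))
  best_cor <- numeric(length(full))
  for (b in seq_along(full)) {
    shifted <- vapply(lags, function(l) pc1[core_of(full[b] + l)], numeric(Lc))
    cors <- suppressWarnings(as.numeric(cor(pc_tpl, shifted)))
    cors[is.na(cors)] <- -Inf
    k <- which.max(cors)
    # parabolic refinement of the correlation peak -> sub-sample lag
    delta <- 0
    if (k > 1 && k < length(lags) && all(is.finite(cors[(k - 1):(k + 1)]))) {
      denom <- cors[k - 1] - 2 * cors[k] + cors[k + 1]
      if (denom < 0) delta <- max(-0.5, min(0.5, 0.5 * (cors[k - 1] - cors[k + 1]) / denom))
      if (abs(delta) < 0.01) delta <- 0   # keep integer-aligned beats exact
    }
    best_lag[b] <- lags[k] + delta
    best_cor[b] <- cors[k]
  }
  retained <- which(best_cor >= corr_threshold)
  if (length(retained) < 3) {
    stop(structure(class = c("ecglvh_extraction_failure", "error", "condition"),
                   list(message = sprintf(
                     "median-beat extraction failed for %s: %d beat(s) retained, need >= 3",
                     ecg$participant_id %||% "<unknown>", length(retained)),
                     call = NULL, participant_id = ecg$participant_id)))
  }
  aligned_peaks <- full[retained] + best_lag[retained]
  acc <- matrix(0, nrow = L, ncol = ncol(ecg$samples))
  for (p in aligned_peaks) {
    p0 <- floor(p)
    f <- p - p0
    w <- avg_src[window_of(p0), , drop = FALSE]
    if (f > 1e-9) {
      w <- (1 - f) * w + f * avg_src[window_of(p0 + 1L), , drop = FALSE]
    }
    acc <- acc + subtract_baseline(w, fs)
  }
  avg <- acc / length(aligned_peaks)
  colnames(avg) <- colnames(ecg$samples)

  # mean R-R over adjacent retained beats; intervals spanning a missed
  # or rejected beat (~ multiples of the typical cycle) are excluded
  rr_raw <- diff(aligned_peaks)
  med_rr <- median(rr_raw)
  rr <- rr_raw[diff(retained) == 1 & rr_raw < 1.5 * med_rr & rr_raw > 0.5 * med_rr]
  if (!length(rr)) rr <- med_rr
  mean_rr_ms <- mean(rr) / fs * 1000

  structure(list(participant_id = ecg$participant_id,
                 waveforms = avg, lead_names = colnames(avg),
                 sampling_rate_hz = fs, r_index = pre + 1L,
                 mean_rr_ms = mean_rr_ms,
                 ventricular_rate_bpm = 60000 / mean_rr_ms,
                 n_beats_detected = length(full),
                 n_beats_retained = length(retained),
                 retained_peaks = aligned_peaks,
                 rejected_peaks = full[setdiff(seq_along(full), retained)]),
            class = "median_beat")
}

#' @export
print.median_beat <- function(x, ...) {
  cat(sprintf("Median beat %s: %d x %d @ %g Hz, rate %.1f bpm (%d/%d beats retained)\n",
              x$participant_id %||% "", nrow(x$waveforms), ncol(x$waveforms),
              x$sampling_rate_hz, x$ventricular_rate_bpm,
              x$n_beats_retained, x$n_beats_detected))
  invisible(x)
}

#' Metadata feature manifest
#'
#' Fixed ordering of the 15 metadata entries fed to the network alongside
#' the ECG: age, sex, BMI, adjusted systolic/diastolic BP, hypertension,
#' diabetes, hypercholesterolaemia, adjusted total and non-HDL
#' cholesterol, alcohol status, smoking one-hot (never/previous/current)
#' and ventricular rate.
#'
#' @return character vector of the 15 column names, with attribute
#'   `continuous` naming the min-max normalized subset.
#' @export
metadata_manifest <- function() {
  cols <- c("age", "sex", "bmi", "sbp_adj", "dbp_adj", "hypertension",
            "diabetes", "hypercholesterolaemia", "total_chol_adj",
            "non_hdl_adj", "alcohol", "smoking_never", "smoking_previous",
            "smoking_current", "ventricular_rate_bpm")
  attr(cols, "continuous") <- c("age", "bmi", "sbp_adj", "dbp_adj",
                                "total_chol_adj", "non_hdl_adj",
                                "ventricular_rate_bpm")
  cols
}

#' Assemble the raw (un-normalized) metadata table
#'
#' Encodes a clinical profile plus the median-beat ventricular rate into
#' the fixed 15-column numeric layout of [metadata_manifest()]: binary
#' variables as 0/1, smoking one-hot encoded, continuous variables left
#' on their natural scale (normalize with [normalize_features()]).
#'
#' @param profile data.frame with derived clinical columns (see
#'   [sample_clinical_profile()]).
#' @param ventricular_rate_bpm numeric vector aligned with `profile`
#'   (ignored if `profile` already has a `ventricular_rate_bpm` column).
#' @return numeric data.frame with the 15 manifest columns.
#' @export
metadata_features <- function(profile, ventricular_rate_bpm = NULL) {
  if (!is.null(ventricular_rate_bpm)) profile$ventricular_rate_bpm <- ventricular_rate_bpm
  need <- c("age", "sex", "bmi", "sbp_adj", "dbp_adj", "hypertension",
            "diabetes", "hypercholesterolaemia", "total_chol_adj",
            "non_hdl_adj", "alcohol", "smoking", "ventricular_rate_bpm")
  missing_cols <- setdiff(need, names(profile))
  if (length(missing_cols)) {
    stop_invalid("metadata assembly: missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  smoking <- as.character(profile$smoking)
  bad <- setdiff(unique(smoking), c("never", "previous", "current"))
  if (length(bad)) stop_invalid("unknown smoking level(s): %s", paste(bad, collapse = ", "))
  out <- data.frame(
    age = profile$age,
    sex = as_sex(profile$sex),
    bmi = profile$bmi,
    sbp_adj = profile$sbp_adj,
    dbp_adj = profile$dbp_adj,
    hypertension = as.numeric(profile$hypertension),
    diabetes = as.numeric(profile$diabetes),
    hypercholesterolaemia = as.numeric(profile$hypercholesterolaemia),
    total_chol_adj = profile$total_chol_adj,
    non_hdl_adj = profile$non_hdl_adj,
    alcohol = as.numeric(profile$alcohol == "current"),
    smoking_never = as.numeric(smoking == "never"),
    smoking_previous = as.numeric(smoking == "previous"),
    smoking_current = as.numeric(smoking == "current"),
    ventricular_rate_bpm = profile$ventricular_rate_bpm
  )
  if (anyNA(out)) stop_invalid("metadata assembly: NA present (impute first)")
  out
}

#' Fit min-max normalization statistics on the training partition
#'
#' Stores the per-feature minimum and maximum of every continuous
#' metadata feature, computed exclusively from the training split, plus
#' the frozen feature-order manifest. Constant features are an error.
#'
#' @param train_metadata data.frame from [metadata_features()] for the
#'   training participants only.
#' @return object of class `normalization_stats`.
#' @export
fit_normalization <- function(train_metadata) {
  manifest <- metadata_manifest()
  cont <- attr(manifest, "continuous")
  missing_cols <- setdiff(manifest, names(train_metadata))
  if (length(missing_cols)) {
    stop_invalid("fit_normalization: missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  mins <- vapply(cont, function(cn) min(train_metadata[[cn]]), numeric(1))
  maxs <- vapply(cont, function(cn) max(train_metadata[[cn]]), numeric(1))
  degenerate <- cont[maxs <= mins]
  if (length(degenerate)) {
    stop_invalid("degenerate (constant) feature(s): %s",
                 paste(degenerate, collapse = ", "))
  }
  structure(list(manifest = as.character(manifest), continuous = cont,
                 min = mins, max = maxs),
            class = "normalization_stats")
}

#' Apply / invert min-max normalization
#'
#' Continuous features are affinely mapped so the training minimum is 0
#' and maximum is 1; values outside the training range extrapolate (no
#' clipping). Binary and one-hot columns pass through unchanged.
#'
#' @param metadata data.frame from [metadata_features()].
#' @param stats a `normalization_stats` object.
#' @return numeric matrix with columns in manifest order.
#' @export
normalize_features <- function(metadata, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  m <- as.matrix(metadata[, stats$manifest, drop = FALSE])
  for (cn in stats$continuous) {
    m[, cn] <- (m[, cn] - stats$min[[cn]]) / (stats$max[[cn]] - stats$min[[cn]])
  }
  m
}

#' @rdname normalize_features
#' @param normalized numeric matrix produced by [normalize_features()].
#' @export
denormalize_features <- function(normalized, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  m <- normalized
  for (cn in stats$continuous) {
    m[, cn] <- m[, cn] * (stats$max[[cn]] - stats$min[[cn]]) + stats$min[[cn]]
  }
  m
}

#' Assemble the model input for one participant
#'
#' Combines the median-beat waveforms (mV, optionally resampled to the
#' network's input rate) with the normalized 15-entry metadata vector.
#' The waveform itself is never normalized.
#'
#' @param beat a `median_beat`.
#' @param profile single-row clinical data.frame (post-imputation).
#' @param stats a `normalization_stats` fitted on the training split.
#' @param model_fs network input rate, Hz (default 100; `NULL` keeps the
#'   beat's native rate).
#' @return list with `ecg` (L_model x 8 matrix) and `metadata` (numeric
#'   vector of length 15).
#' @export
build_feature_vector <- function(beat, profile, stats, model_fs = 100) {
  stopifnot(inherits(beat, "median_beat"))
  wf <- beat$waveforms
  if (!is.null(model_fs) && model_fs != beat$sampling_rate_hz) {
    wf <- resample_beat(wf, beat$sampling_rate_hz, model_fs)
  }
  md <- metadata_features(profile, ventricular_rate_bpm = beat$ventricular_rate_bpm)
  v <- as.numeric(normalize_features(md, stats)[1, ])
  names(v) <- stats$manifest
  list(ecg = wf, metadata = v)
}

# Linear resampling of a beat matrix (L x leads) to a new rate.
resample_beat <- function(wf, fs, target_fs) {
  L <- nrow(wf)
  t_old <- (seq_len(L) - 1) / fs
  Lm <- round(L / fs * target_fs)
  t_new <- (seq_len(Lm) - 1) / target_fs
  out <- vapply(seq_len(ncol(wf)), function(j) {
    approx(t_old, wf[, j], xout = t_new, rule = 2)$y
  }, numeric(Lm))
  colnames(out) <- colnames(wf)
  out
}

#' Mode / median imputation of missing clinical values
#'
#' Continuous columns are filled with the median of the non-missing
#' values, binary and categorical columns with the mode, computed over
#' the same table (i.e. the same cohort split). Fully missing columns
#' are an error naming the column.
#'
#' @param profiles data.frame of clinical covariates.
#' @return `profiles` with no missing values.
#' @export
impute_missing <- function(profiles) {
  for (cn in names(profiles)) {
    v <- profiles[[cn]]
    if (!anyNA(v)) next
    if (all(is.na(v))) stop_invalid("cannot impute fully-missing column '%s'", cn)
    obs <- v[!is.na(v)]
    if (is.numeric(obs) && length(setdiff(unique(obs), c(0, 1))) > 0) {
      fill <- median(obs)
    } else {
      tab <- sort(table(obs), decreasing = TRUE)
      fill <- names(tab)[1]
      if (is.numeric(obs)) fill <- as.numeric(fill)
      if (is.logical(v)) fill <- as.logical(fill)
    }
    v[is.na(v)] <- fill
    profiles[[cn]] <- v
  }
  profiles
}
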