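# LVH decision rules on top of iLVM predictions: fixed reference
# thresholds, logistic recalibration with sex as covariate (adaptive
# cut-offs), and the classical Sokolow-Lyon / Cornell voltage criteria
# measured on median beats.

#' Classify LVH by the published reference thresholds
#'
#' Flag = iLVM > 70 g/m^2 (males) or > 55 g/m^2 (females), strict
#' inequalities, applied to predicted iLVM.
#'
#' @param predicted_ilvm numeric vector, g/m^2.
#' @param sex any encoding accepted by [as_sex()].
#' @return logical vector.
#' @export
classify_by_reference_threshold <- function(predicted_ilvm, sex) {
  if (any(!is.finite(predicted_ilvm))) stop_invalid("predicted_ilvm must be finite")
  sex <- as_sex(sex)
  thr <- ifelse(sex == 1L, lvh_thresholds()[["male"]], lvh_thresholds()[["female"]])
  predicted_ilvm > thr
}

#' Fit the logistic recalibration of iLVM predictions
#'
#' Logistic regression of the true LVH label on (predicted iLVM, sex)
#' with per-sample class-balancing weights n / (2 * n_class), i.e. the
#' total weight of each class is equal. The fitted model defines
#' adaptive, sex-specific iLVM decision cut-offs that compensate for
#' systematically skewed predictions.
#'
#' @param predicted_ilvm numeric predictions, g/m^2.
#' @param sex any encoding accepted by [as_sex()].
#' @param true_lvh logical (or 0/1) ground-truth labels; both classes
#'   must be present.
#' @return object of class `lvh_recalibration` with elements `intercept`,
#'   `beta_ilvm`, `beta_sex`, `weighting`, `n`.
#' @export
fit_recalibration <- function(predicted_ilvm, sex, true_lvh) {
  y <- as.numeric(true_lvh)
  if (length(unique(y)) < 2) stop_invalid("both classes must be present to recalibrate")
  sex <- as_sex(sex)
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  df <- data.frame(y = y, ilvm = predicted_ilvm, sex = sex)
  # quasibinomial: identical point estimates to binomial, without the
  # non-integer-successes warning triggered by fractional weights
  fit <- glm(y ~ ilvm + sex, family = quasibinomial(), data = df, weights = w,
             control = list(maxit = 100))
  cf <- coef(fit)
  if (any(!is.finite(cf))) {
    stop_invalid("recalibration logistic regression did not converge (non-finite coefficients)")
  }
  if (!fit$converged) {
    # complete separation: the coefficients diverge but their ratios (the
    # implied iLVM cut-offs) remain identifiable
    warning("recalibration fit did not fully converge (likely class separation); implied cut-offs remain valid",
            call. = FALSE)
  }
  structure(list(intercept = unname(cf[["(Intercept)"]]),
                 beta_ilvm = unname(cf[["ilvm"]]), beta_sex = unname(cf[["sex"]]),
                 weighting = "balanced (n / (2 * n_class))", n = n),
            class = "lvh_recalibration")
}

#' @export
print.lvh_recalibration <- function(x, ...) {
  co <- cutoffs_from_recalibration(x)
  cat(sprintf("LVH recalibration (n = %d): logit(p) = %.3f + %.4f * iLVM + %.3f * sex\n",
              x$n, x$intercept, x$beta_ilvm, x$beta_sex))
  cat(sprintf("  implied cut-offs: male %.1f g/m^2, female %.1f g/m^2\n",
              co[["male"]], co[["female"]]))
  invisible(x)
}

#' Predict LVH probability from a recalibration model
#'
#' @param object an `lvh_recalibration`.
#' @param predicted_ilvm numeric predictions, g/m^2.
#' @param sex any encoding accepted by [as_sex()].
#' @param ... unused.
#' @return numeric probabilities in (0, 1).
#' @export
predict.lvh_recalibration <- function(object, predicted_ilvm, sex, ...) {
  sex <- as_sex(sex)
  eta <- object$intercept + object$beta_ilvm * predicted_ilvm + object$beta_sex * sex
  1 / (1 + exp(-eta))
}

#' Sex-specific iLVM cut-offs implied by the recalibration
#'
#' The predicted-iLVM value at which the recalibrated class probability
#' is exactly 0.5: cutoff(sex) = -(intercept + beta_sex * sex) /
#' beta_ilvm. Requires a positive iLVM coefficient (the model must be
#' monotone increasing in iLVM).
#'
#' @param model an `lvh_recalibration`.
#' @return named numeric vector `c(male =, female =)`, g/m^2.
#' @export
cutoffs_from_recalibration <- function(model) {
  stopifnot(inherits(model, "lvh_recalibration"))
  if (model$beta_ilvm <= 0) {
    stop_invalid("recalibration is not monotone increasing in iLVM (beta_ilvm <= 0)")
  }
  c(male = -(model$intercept + model$beta_sex) / model$beta_ilvm,
    female = -model$intercept / model$beta_ilvm)
}

#' Measure R-wave amplitudes and S-wave depths on a median beat
#'
#' Within a QRS window of +/- 80 ms around the beat's alignment point,
#' after subtracting a baseline (median of the earliest 100 ms of the
#' window): R = largest positive deflection; S = largest negative
#' deflection occurring at or after the R peak (stored positive). The
#' augmented lead aVL is derived samplewise as I - II/2 before
#' measurement.
#'
#' @param beat a `median_beat`.
#' @param qrs_half_window_ms QRS search half-width around the R
#'   alignment point, ms.
#' @return object of class `voltage_measurements`: data.frame with
#'   columns `lead`, `r_mv`, `s_mv` for V1, V3, V5, V6 and aVL.
#' @export
measure_wave_amplitudes <- function(beat, qrs_half_window_ms = 80) {
  stopifnot(inherits(beat, "median_beat"))
  fs <- beat$sampling_rate_hz
  wf <- beat$waveforms
  need <- c("I", "II", "V1", "V3", "V5", "V6")
  missing_leads <- setdiff(need, colnames(wf))
  if (length(missing_leads)) {
    stop_invalid("median beat is missing lead(s): %s", paste(missing_leads, collapse = ", "))
  }
  avl <- wf[, "I"] - wf[, "II"] / 2
  mat <- cbind(wf[, c("V1", "V3", "V5", "V6")], aVL = avl)
  half <- round(qrs_half_window_ms / 1000 * fs)
  r0 <- beat$r_index
  win <- max(1, r0 - half):min(nrow(mat), r0 + half)
  if (r0 - half < 1 || r0 + half > nrow(mat)) {
    stop_invalid("QRS window extends outside the beat window")
  }
  base_rows <- seq_len(max(1, round(0.1 * fs)))
  out <- lapply(colnames(mat), function(ld) {
    y <- mat[, ld] - median(mat[base_rows, ld])
    seg <- y[win]
    r_amp <- max(0, max(seg))
    r_pos <- which.max(seg)
    s_amp <- max(0, -min(seg[r_pos:length(seg)]))
    data.frame(lead = ld, r_mv = r_amp, s_mv = s_amp, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("voltage_measurements", "data.frame"))
}

voltage_lookup <- function(v, lead, what) {
  row <- v[v$lead == lead, ]
  if (!nrow(row)) stop_invalid("measurement for lead %s is missing", lead)
  row[[what]]
}

#' Sokolow-Lyon voltage criterion
#'
#' Index = S depth in V1 + max(R amplitude in V5, V6); positive when the
#' index is >= 3.5 mV (35 mm at standard calibration).
#'
#' @param v a `voltage_measurements`.
#' @return list with `index_mv` and logical `positive`.
#' @export
sokolow_lyon <- function(v) {
  idx <- voltage_lookup(v, "V1", "s_mv") +
    max(voltage_lookup(v, "V5", "r_mv"), voltage_lookup(v, "V6", "r_mv"))
  list(index_mv = idx, positive = idx >= 3.5)
}

#' Cornell voltage criterion
#'
#' Index = R amplitude in aVL + S depth in V3; positive when the index
#' exceeds 2.8 mV in males or 2.0 mV in females (strict inequality).
#'
#' @param v a `voltage_measurements`.
#' @param sex any encoding accepted by [as_sex()].
#' @return list with `index_mv`, `threshold_mv` and logical `positive`.
#' @export
cornell_voltage <- function(v, sex) {
  sex <- as_sex(sex)
  idx <- voltage_lookup(v, "aVL", "r_mv") + voltage_lookup(v, "V3", "s_mv")
  thr <- if (sex == 1L) 2.8 else 2.0
  list(index_mv = idx, threshold_mv = thr, positive = idx > thr)
}
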