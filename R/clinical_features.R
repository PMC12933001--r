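# Clinical-variable derivation: CMR indexing and LVH labelling, medication
# adjustments, condition definitions and cohort splitting.

#' Sex-specific indexed LVM thresholds defining LVH
#'
#' Indexed left ventricular mass (g/m^2) above which a participant is
#' labelled as having left ventricular hypertrophy, by sex. These are the
#' published upper reference limits for CMR-derived iLVM (strict
#' inequality: a value exactly at the threshold is normal).
#'
#' @return named numeric vector with elements `male` (70) and `female` (55).
#' @export
lvh_thresholds <- function() c(male = 70, female = 55)

#' Body surface area by the Mosteller formula
#'
#' BSA = sqrt(height_cm * weight_kg / 3600), in m^2.
#'
#' @param height_cm height in centimetres (> 0).
#' @param weight_kg weight in kilograms (> 0).
#' @return numeric vector of body surface areas in m^2.
#' @examples
#' mosteller_bsa(180, 72) # 1.897
#' @export
mosteller_bsa <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0, na.rm = TRUE) || any(weight_kg <= 0, na.rm = TRUE)) {
    stop_invalid("height and weight must be positive")
  }
  sqrt(height_cm * weight_kg / 3600)
}

#' Index LV mass to body surface area and assign the LVH label
#'
#' Computes BSA (Mosteller), indexed LVM = LVM / BSA, and the sex-specific
#' LVH label (iLVM > 70 g/m^2 for males, > 55 g/m^2 for females; strict
#' inequalities).
#'
#' @param lvm_g left ventricular mass in grams (> 0).
#' @param height_cm,weight_kg body size used for indexing (> 0).
#' @param sex sex in any encoding accepted by [as_sex()].
#' @return data.frame with columns `bsa_m2`, `ilvm`, `lvh_label`.
#' @export
index_and_label <- function(lvm_g, height_cm, weight_kg, sex) {
  if (any(lvm_g <= 0, na.rm = TRUE)) stop_invalid("lvm_g must be positive")
  sex <- as_sex(sex)
  bsa <- mosteller_bsa(height_cm, weight_kg)
  ilvm <- lvm_g / bsa
  thr <- ifelse(sex == 1L, lvh_thresholds()[["male"]], lvh_thresholds()[["female"]])
  data.frame(bsa_m2 = bsa, ilvm = ilvm, lvh_label = ilvm > thr)
}

#' Adjust blood pressure for antihypertensive treatment
#'
#' Participants on BP-lowering medication have 15 mmHg added to systolic
#' and 10 mmHg to diastolic readings; untreated readings pass through
#' unchanged. Readings outside the physiological ranges (systolic 70-300,
#' diastolic 30-200 mmHg) trigger a warning but are not altered.
#'
#' @param sbp_raw,dbp_raw averaged systolic/diastolic readings, mmHg.
#' @param on_bp_medication logical flag (vectorised).
#' @return data.frame with columns `sbp_adj`, `dbp_adj`.
#' @export
adjust_bp <- function(sbp_raw, dbp_raw, on_bp_medication) {
  out_of_range <- (sbp_raw < 70 | sbp_raw > 300 | dbp_raw < 30 | dbp_raw > 200)
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sprintf("%d BP reading(s) outside physiological range; passed through",
                    sum(out_of_range, na.rm = TRUE)), call. = FALSE)
  }
  med <- as.logical(on_bp_medication)
  data.frame(sbp_adj = sbp_raw + ifelse(med, 15, 0),
             dbp_adj = dbp_raw + ifelse(med, 10, 0))
}

#' Adjust cholesterol for lipid-lowering treatment
#'
#' Treated participants' total and non-HDL cholesterol are divided by 0.73
#' and 0.66 respectively (i.e. scaled up to an estimated untreated level);
#' untreated values pass through unchanged.
#'
#' @param total_raw,non_hdl_raw serum cholesterol, mmol/L (> 0).
#' @param on_lipid_medication logical flag (vectorised).
#' @return data.frame with columns `total_chol_adj`, `non_hdl_adj`.
#' @export
adjust_cholesterol <- function(total_raw, non_hdl_raw, on_lipid_medication) {
  if (any(total_raw <= 0, na.rm = TRUE) || any(non_hdl_raw <= 0, na.rm = TRUE)) {
    stop_invalid("cholesterol values must be positive")
  }
  med <- as.logical(on_lipid_medication)
  data.frame(total_chol_adj = total_raw / ifelse(med, 0.73, 1),
             non_hdl_adj = non_hdl_raw / ifelse(med, 0.66, 1))
}

#' Derive condition flags from adjusted clinical measurements
#'
#' Adds `hypertension`, `diabetes` and `hypercholesterolaemia` columns:
#' * hypertension: formal diagnosis, BP medication, or adjusted BP
#'   exceeding 130/85 mmHg (strict `>` on either component);
#' * diabetes: HbA1c >= 48 mmol/mol;
#' * hypercholesterolaemia: adjusted total cholesterol >= 5 mmol/L.
#'
#' The BP component uses treatment-adjusted readings by default; set
#' `use_adjusted_bp = FALSE` to apply the cut-off to raw readings instead
#' (columns `sbp_raw`/`dbp_raw` must then be present).
#'
#' @param profile data.frame with columns `hypertension_dx`,
#'   `on_bp_medication`, `sbp_adj`, `dbp_adj`, `hba1c`, `total_chol_adj`.
#' @param use_adjusted_bp logical; apply the 130/85 cut-off to adjusted
#'   (default) or raw BP.
#' @return `profile` with the three derived flag columns set.
#' @export
derive_conditions <- function(profile, use_adjusted_bp = TRUE) {
  need <- c("hypertension_dx", "on_bp_medication", "hba1c", "total_chol_adj",
            if (use_adjusted_bp) c("sbp_adj", "dbp_adj") else c("sbp_raw", "dbp_raw"))
  missing_cols <- setdiff(need, names(profile))
  if (length(missing_cols)) {
    stop_invalid("derive_conditions: missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  if (anyNA(profile[need])) {
    stop_invalid("derive_conditions: NA in required columns (impute first)")
  }
  sbp <- if (use_adjusted_bp) profile$sbp_adj else profile$sbp_raw
  dbp <- if (use_adjusted_bp) profile$dbp_adj else profile$dbp_raw
  profile$hypertension <- as.logical(profile$hypertension_dx) |
    as.logical(profile$on_bp_medication) | (sbp > 130) | (dbp > 85)
  profile$diabetes <- profile$hba1c >= 48
  profile$hypercholesterolaemia <- profile$total_chol_adj >= 5
  profile
}

#' Split participant ids into train / validation / test sets
#'
#' Seeded uniform shuffle followed by a contiguous partition. Realized
#' sizes are `round(n * fraction)` for the first two sets and the
#' remainder for the test set (within one participant of the targets).
#' Optionally stratified: the split is performed within each stratum and
#' the pieces concatenated.
#'
#' @param ids vector of participant identifiers.
#' @param fractions numeric length-3 vector (train, validation, test)
#'   summing to 1.
#' @param seed integer seed making the shuffle reproducible.
#' @param stratify_by optional vector aligned with `ids`; when given, the
#'   split is applied within each level.
#' @return object of class `cohort_split`: list with `train_ids`,
#'   `validation_ids`, `test_ids`, `fractions`, `seed`.
#' @export
split_cohort <- function(ids, fractions = c(0.7, 0.15, 0.15), seed = 1L,
                         stratify_by = NULL) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    stop_invalid("fractions must be length 3 and sum to 1")
  }
  if (anyDuplicated(ids)) stop_invalid("ids must be unique")
  split_one <- function(v, s) {
    n <- length(v)
    perm <- with_seed(s, sample.int(n))
    v <- v[perm]
    n_train <- round(n * fractions[1])
    n_val <- round(n * fractions[2])
    if (n_train + n_val > n) n_val <- n - n_train
    list(train = v[seq_len(n_train)],
         validation = if (n_val > 0) v[n_train + seq_len(n_val)] else v[0],
         test = if (n - n_train - n_val > 0) v[(n_train + n_val + 1):n] else v[0])
  }
  if (is.null(stratify_by)) {
    parts <- split_one(ids, seed)
  } else {
    stopifnot(length(stratify_by) == length(ids))
    lv <- unique(stratify_by)
    pieces <- lapply(seq_along(lv), function(k) {
      split_one(ids[stratify_by == lv[k]], derive_seed(seed, k))
    })
    parts <- list(train = unlist(lapply(pieces, `[[`, "train")),
                  validation = unlist(lapply(pieces, `[[`, "validation")),
                  test = unlist(lapply(pieces, `[[`, "test")))
  }
  structure(list(train_ids = parts$train, validation_ids = parts$validation,
                 test_ids = parts$test, fractions = fractions, seed = seed),
            class = "cohort_split")
}
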