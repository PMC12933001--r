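# Integrated-gradients attribution over ECG samples and metadata, with
# background (baseline) averaging, plus the 5th/95th-percentile group
# waveform contrasts.

# Gradient of the network output with respect to the ECG input and the
# metadata, in inference mode (internal). X: (L, C, N) array.
fcn_input_gradient <- function(model, ecg_arr, metadata) {
  r <- cpp_pass(model, ecg_arr, metadata, mode = 2L)
  dX <- r$d_input       # (L*N, C), time fastest
  d <- dim(ecg_arr)
  dim(dX) <- c(d[1], d[3], d[2])
  list(value = as.numeric(r$pred), d_ecg = aperm(dX, c(1, 3, 2)),
       d_metadata = r$d_metadata)
}

#' Integrated-gradients attribution for one participant
#'
#' For each baseline x', approximates (x - x') * integral over alpha of
#' the model gradient along the straight path from x' to x (midpoint
#' Riemann sum with `steps` points), then averages the attributions over
#' baselines. The completeness residual |sum(attributions) - (F(x) -
#' mean F(x'))| is recorded; it vanishes as `steps` grows.
#'
#' @param model a trained `fcn_model`, or a function
#'   `function(ecg_arr, metadata)` returning `list(value, d_ecg,
#'   d_metadata)` for a batch (ecg_arr is L x leads x N), which lets the
#'   attribution engine run over arbitrary differentiable models.
#' @param input list with `ecg` (L x leads matrix) and `metadata`
#'   (numeric vector), as from [build_feature_vector()].
#' @param background `fcn_features` (or list of feature vectors) holding
#'   the baseline sample; non-empty.
#' @param steps number of Riemann points (>= 1).
#' @return object of class `attribution_map`: `ecg_attributions` (L x
#'   leads), `metadata_attributions` (named vector), `prediction`,
#'   `baseline_prediction` (mean over baselines), `completeness_residual`,
#'   `n_background`, `n_path_steps`.
#' @export
integrated_gradients <- function(model, input, background, steps = 50) {
  if (steps < 1) stop_invalid("steps must be >= 1")
  if (inherits(background, "fcn_features")) {
    nb <- dim(background$ecg)[3]
    bg_ecg <- background$ecg
    bg_meta <- background$metadata
  } else {
    nb <- length(background)
    if (!nb) stop_invalid("background must be non-empty")
    bg_ecg <- simplify2array(lapply(background, `[[`, "ecg"))
    bg_meta <- do.call(rbind, lapply(background, `[[`, "metadata"))
  }
  if (is.null(bg_meta)) bg_meta <- matrix(0, nb, 0L)
  if (!nb) stop_invalid("background must be non-empty")
  L <- nrow(input$ecg)
  C <- ncol(input$ecg)
  is_fcn <- inherits(model, "fcn_model")
  grad_fn <- if (is_fcn) {
    function(ecg_arr, metadata) fcn_input_gradient(model, ecg_arr, metadata)
  } else if (is.function(model)) {
    model
  } else {
    stop_invalid("model must be an fcn_model or a gradient function")
  }
  use_meta <- if (is_fcn) model$config$metadata_dim > 0 else length(input$metadata) > 0
  n_meta <- length(input$metadata)

  diff_ecg <- array(rep(input$ecg, nb), c(L, C, nb)) - bg_ecg
  diff_meta <- if (use_meta) {
    matrix(input$metadata, nrow = nb, ncol = length(input$metadata),
           byrow = TRUE) - bg_meta
  } else NULL

  grad_ecg_sum <- array(0, c(L, C, nb))
  grad_meta_sum <- if (use_meta) matrix(0, nb, n_meta) else NULL
  alphas <- (seq_len(steps) - 0.5) / steps
  for (a in alphas) {
    ecg_a <- bg_ecg + a * diff_ecg
    meta_a <- if (use_meta) bg_meta + a * diff_meta else matrix(0, nb, 0L)
    g <- grad_fn(ecg_a, meta_a)
    if (!all(is.finite(g$d_ecg))) stop_invalid("non-finite gradients along the path")
    grad_ecg_sum <- grad_ecg_sum + g$d_ecg
    if (use_meta) grad_meta_sum <- grad_meta_sum + g$d_metadata
  }
  attr_ecg_per_bg <- diff_ecg * grad_ecg_sum / steps
  ecg_attr <- apply(attr_ecg_per_bg, c(1, 2), mean)
  colnames(ecg_attr) <- colnames(input$ecg)
  meta_attr <- if (use_meta) {
    colMeans(diff_meta * grad_meta_sum / steps)
  } else numeric(0)
  if (use_meta) names(meta_attr) <- names(input$metadata)

  pred <- grad_fn(array(input$ecg, c(L, C, 1)),
                  matrix(input$metadata, nrow = 1))$value
  bg_pred <- mean(grad_fn(bg_ecg, bg_meta)$value)
  total <- sum(ecg_attr) + sum(meta_attr)
  structure(list(ecg_attributions = ecg_attr,
                 metadata_attributions = meta_attr,
                 prediction = pred, baseline_prediction = bg_pred,
                 completeness_residual = abs(total - (pred - bg_pred)),
                 n_background = nb, n_path_steps = steps),
            class = "attribution_map")
}

#' Rank metadata features by mean absolute attribution
#'
#' Aggregates attribution maps over a split into a ranked feature table
#' with the signed per-participant attribution distributions (beeswarm-
#' ready long format in the `values` attribute).
#'
#' @param maps list of `attribution_map` objects (>= 1).
#' @return data.frame with columns `feature`, `mean_abs_attribution`,
#'   `mean_attribution`, ranked descending.
#' @export
metadata_importance_summary <- function(maps) {
  if (!length(maps)) stop_invalid("need at least one attribution map")
  m <- do.call(rbind, lapply(maps, `[[`, "metadata_attributions"))
  out <- data.frame(feature = colnames(m),
                    mean_abs_attribution = colMeans(abs(m)),
                    mean_attribution = colMeans(m),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_attribution), ]
  rownames(out) <- NULL
  attr(out, "values") <- m
  out
}

#' Mean waveforms of the extreme-prediction groups
#'
#' Splits participants by the empirical 5th/95th percentiles of
#' predicted iLVM and returns per-lead pointwise mean and SD waveforms
#' for the low and high groups.
#'
#' @param predictions numeric predicted iLVM per participant.
#' @param beats list of `median_beat` objects (aligned with
#'   `predictions`) or an (L x leads x N) array.
#' @param lower,upper percentile bounds (defaults 0.05 and 0.95).
#' @return list with `low` and `high`, each holding `mask`, `mean`
#'   (L x leads) and `sd`.
#' @export
percentile_group_waveforms <- function(predictions, beats, lower = 0.05,
                                       upper = 0.95) {
  n <- length(predictions)
  if (n < 20) stop_invalid("need at least 20 participants")
  qs <- quantile(predictions, c(lower, upper))
  if (qs[1] == qs[2]) stop_invalid("degenerate prediction percentiles (constant predictions)")
  low_mask <- predictions < qs[1]
  high_mask <- predictions > qs[2]
  if (!any(low_mask) || !any(high_mask)) stop_invalid("an extreme group is empty")
  arr <- if (is.array(beats) && length(dim(beats)) == 3) beats
         else simplify2array(lapply(beats, `[[`, "waveforms"))
  grp <- function(mask) {
    sub <- arr[, , mask, drop = FALSE]
    list(mask = mask,
         mean = apply(sub, c(1, 2), mean),
         sd = apply(sub, c(1, 2), sd))
  }
  list(low = grp(low_mask), high = grp(high_mask),
       bounds = unname(qs))
}
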