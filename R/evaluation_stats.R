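# Diagnostic and regression statistics: empirical AUROC (Mann-Whitney),
# Hanley-McNeil analytic confidence intervals, the fast (midrank) DeLong
# test for paired AUROCs, Youden-J operating points, confusion-matrix
# metrics with Wilson intervals, bootstrap error intervals and
# Bland-Altman agreement.

check_binary_labels <- function(labels) {
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop_invalid("labels must be binary (0/1 or logical)")
  if (length(unique(y)) < 2) stop_invalid("both classes must be present")
  y
}

#' Empirical AUROC (Mann-Whitney formulation)
#'
#' Fraction of (positive, negative) pairs in which the positive scores
#' higher, with ties counted 1/2; computed via midranks.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels.
#' @return AUROC in [0, 1].
#' @export
auroc_empirical <- function(scores, labels) {
  y <- check_binary_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Analytic (Hanley-McNeil) confidence interval for an AUROC
#'
#' SE = sqrt((A(1-A) + (n1-1)(Q1-A^2) + (n0-1)(Q2-A^2)) / (n1 n0)) with
#' Q1 = A/(2-A) and Q2 = 2A^2/(1+A); the normal interval A +/- z SE is
#' clipped to [0, 1]. Degenerate AUROCs (0 or 1) yield SE 0 with a
#' warning.
#'
#' @param auc point estimate.
#' @param n_pos,n_neg class counts (>= 1).
#' @param conf_level confidence level (default 0.95).
#' @return named numeric vector `c(low, high)` with attribute `se`.
#' @export
auroc_ci_analytic <- function(auc, n_pos, n_neg, conf_level = 0.95) {
  if (n_pos < 1 || n_neg < 1) stop_invalid("class counts must be >= 1")
  if (auc < 0 || auc > 1) stop_invalid("auc must lie in [0, 1]")
  if (auc %in% c(0, 1)) {
    warning("degenerate AUROC; standard error is 0", call. = FALSE)
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(low = max(0, auc - z * se), high = min(1, auc + z * se))
  attr(ci, "se") <- se
  ci
}

# Midrank placement components of the DeLong covariance (internal):
# V10[i] for positives, V01[j] for negatives.
delong_components <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  tz <- rank(c(pos, neg), ties.method = "average")
  tx <- rank(pos, ties.method = "average")
  ty <- rank(neg, ties.method = "average")
  v10 <- (tz[seq_len(n1)] - tx) / n0
  v01 <- 1 - (tz[n1 + seq_len(n0)] - ty) / n1
  auc <- sum(v10) / n1
  list(v10 = v10, v01 = v01, auc = auc, n1 = n1, n0 = n0)
}

#' DeLong test comparing two paired AUROCs
#'
#' Fast midrank implementation of DeLong's nonparametric comparison of
#' correlated AUROCs: the variance of the paired AUROC difference is
#' estimated from the placement components of both score vectors and a
#' two-sided normal p-value is returned. Identical score vectors give
#' z = 0, p = 1.
#'
#' @param scores_a,scores_b paired score vectors on the same
#'   participants.
#' @param labels binary labels.
#' @return list with `z`, `p`, `auc_a`, `auc_b`, `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stop_invalid("scores_a, scores_b and labels must be paired (equal length)")
  }
  y <- check_binary_labels(labels)
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  s10 <- cov(cbind(ca$v10, cb$v10))
  s01 <- cov(cbind(ca$v01, cb$v01))
  s <- s10 / ca$n1 + s01 / ca$n0
  var_diff <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  d <- ca$auc - cb$auc
  if (d == 0 || var_diff <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  list(z = z, p = p, auc_a = ca$auc, auc_b = cb$auc, var_diff = var_diff)
}

#' Youden-J optimized operating point
#'
#' Scans every threshold between distinct sorted scores (classification
#' rule: positive when score > threshold) and returns the threshold
#' maximizing sensitivity + specificity - 1; ties are broken in favour
#' of higher specificity. When even the best J is <= 0 the result
#' carries `degenerate = TRUE`.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return list with `threshold`, `sensitivity`, `specificity`, `j`,
#'   `degenerate`.
#' @export
youden_operating_point <- function(scores, labels) {
  y <- check_binary_labels(labels)
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  sens <- vapply(cand, function(th) sum(scores > th & y == 1) / n1, numeric(1))
  spec <- vapply(cand, function(th) sum(scores <= th & y == 0) / n0, numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(spec[best])]
  list(threshold = cand[best], sensitivity = sens[best], specificity = spec[best],
       j = j[best], degenerate = j[best] <= 0)
}

#' ROC curve coordinates
#'
#' Sensitivity/specificity pairs over every threshold between distinct
#' scores, ready for plotting or CSV export.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return data.frame with columns `threshold`, `tpr`, `fpr`, ordered by
#'   increasing false-positive rate.
#' @export
roc_coordinates <- function(scores, labels) {
  y <- check_binary_labels(labels)
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2,
           u[length(u)] + 1)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  tpr <- vapply(thr, function(th) sum(scores > th & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(th) sum(scores > th & y == 0) / n0, numeric(1))
  out <- data.frame(threshold = thr, tpr = tpr, fpr = fpr)
  out[order(out$fpr, out$tpr), , drop = FALSE]
}

#' Confusion-matrix metrics with Wilson confidence intervals
#'
#' Sensitivity, specificity and F1 from predicted vs true binary labels;
#' sensitivity/specificity intervals are Wilson score intervals.
#'
#' @param labels_pred predicted binary labels.
#' @param labels_true true binary labels (positives must be present for
#'   sensitivity to be defined).
#' @return list with `sensitivity`, `specificity`, `f1`, their CIs and
#'   the confusion counts.
#' @export
binary_metrics <- function(labels_pred, labels_true) {
  yp <- as.numeric(labels_pred)
  yt <- as.numeric(labels_true)
  if (!all(c(yp, yt) %in% c(0, 1))) stop_invalid("labels must be binary")
  tp <- sum(yp == 1 & yt == 1)
  fn <- sum(yp == 0 & yt == 1)
  tn <- sum(yp == 0 & yt == 0)
  fp <- sum(yp == 1 & yt == 0)
  if (tp + fn == 0) stop_invalid("sensitivity undefined: no positives in truth")
  if (tn + fp == 0) stop_invalid("specificity undefined: no negatives in truth")
  wilson <- function(x, n) {
    as.numeric(suppressWarnings(prop.test(x, n, correct = FALSE))$conf.int)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(sensitivity = recall, sensitivity_ci = wilson(tp, tp + fn),
       specificity = tn / (tn + fp), specificity_ci = wilson(tn, tn + fp),
       f1 = f1, counts = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' Regression accuracy report with bootstrap confidence intervals
#'
#' Mean absolute error and mean error (predicted - observed, so
#' systematic underestimation is negative) with seeded percentile
#' bootstrap intervals (participant-level resampling, 5000 replicates by
#' default), residual skewness, Pearson correlation, ordinary
#' least-squares fit (observed ~ predicted is NOT used; the fit is
#' predicted regressed on observed) and adjusted R^2.
#'
#' @param predicted,observed paired numeric vectors (n >= 3).
#' @param n_boot bootstrap replicates.
#' @param conf_level confidence level.
#' @param seed integer seed recorded in the report.
#' @return list of class `regression_report`.
#' @export
regression_report <- function(predicted, observed, n_boot = 5000,
                              conf_level = 0.95, seed = 1L) {
  n <- length(predicted)
  if (length(observed) != n || n < 3) stop_invalid("need paired vectors with n >= 3")
  d <- predicted - observed
  mae <- mean(abs(d))
  me <- mean(d)
  alpha <- (1 - conf_level) / 2
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    dm <- matrix(d[idx], nrow = n_boot)
    cbind(mae = rowMeans(abs(dm)), me = rowMeans(dm))
  })
  ct <- cor.test(predicted, observed)
  fit <- lm(predicted ~ observed)
  sfit <- summary(fit)
  structure(list(
    n = n, mae = mae,
    mae_ci = unname(quantile(boot[, "mae"], c(alpha, 1 - alpha))),
    me = me,
    me_ci = unname(quantile(boot[, "me"], c(alpha, 1 - alpha))),
    residual_skew = sample_skewness(d),
    pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
    ols_slope = unname(coef(fit)[2]), ols_intercept = unname(coef(fit)[1]),
    adj_r_squared = sfit$adj.r.squared,
    n_boot = n_boot, seed = seed
  ), class = "regression_report")
}

#' Bland-Altman limits of agreement
#'
#' Differences d = predicted - observed; bias = mean(d); limits of
#' agreement = bias +/- 1.96 sd(d); each limit's confidence interval has
#' half-width t(0.975, n-1) * sqrt(3 sd^2 / n). Zero-variance input
#' collapses the limits onto the bias with a warning.
#'
#' @param predicted,observed paired numeric vectors (n >= 3).
#' @param conf_level confidence level for the LoA intervals.
#' @return list with `bias`, `loa_low`, `loa_high`, `loa_low_ci`,
#'   `loa_high_ci`, `sd_diff`, `n`.
#' @export
bland_altman <- function(predicted, observed, conf_level = 0.95) {
  n <- length(predicted)
  if (length(observed) != n || n < 3) stop_invalid("need paired vectors with n >= 3")
  d <- predicted - observed
  bias <- mean(d)
  s <- sd(d)
  if (s == 0) {
    warning("zero variance of differences; limits of agreement collapse to the bias",
            call. = FALSE)
  }
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  half <- qt(1 - (1 - conf_level) / 2, n - 1) * sqrt(3 * s^2 / n)
  list(bias = bias, loa_low = loa_low, loa_high = loa_high,
       loa_low_ci = c(loa_low - half, loa_low + half),
       loa_high_ci = c(loa_high - half, loa_high + half),
       sd_diff = s, n = n)
}

#' Full evaluation report for one model's predictions
#'
#' Combines AUROC with its analytic CI, the Youden operating point with
#' Wilson sensitivity/specificity intervals and F1, the regression
#' accuracy report and Bland-Altman agreement (when continuous iLVM
#' predictions are supplied), and an optional DeLong comparison against
#' a named comparator score vector.
#'
#' @param scores continuous scores used for ranking (probabilities or
#'   predicted iLVM).
#' @param labels true binary LVH labels.
#' @param predicted_ilvm,observed_ilvm optional paired continuous values
#'   for the regression/agreement section.
#' @param comparator optional list `list(name =, scores =)` for a DeLong
#'   comparison.
#' @param n_boot bootstrap replicates for the regression section.
#' @param seed integer seed.
#' @return list of class `evaluation_report`.
#' @export
evaluation_report <- function(scores, labels, predicted_ilvm = NULL,
                              observed_ilvm = NULL, comparator = NULL,
                              n_boot = 5000, seed = 1L) {
  y <- check_binary_labels(labels)
  auc <- auroc_empirical(scores, y)
  ci <- auroc_ci_analytic(auc, sum(y == 1), sum(y == 0))
  yj <- youden_operating_point(scores, y)
  bm <- binary_metrics(as.numeric(scores > yj$threshold), y)
  rep <- list(n = length(y), n_positive = sum(y == 1),
              auroc = auc, auroc_ci = unname(ci),
              youden = yj, metrics = bm, threshold = yj$threshold)
  if (!is.null(predicted_ilvm) && !is.null(observed_ilvm)) {
    rep$regression <- regression_report(predicted_ilvm, observed_ilvm,
                                        n_boot = n_boot, seed = seed)
    rep$bland_altman <- bland_altman(predicted_ilvm, observed_ilvm)
  }
  if (!is.null(comparator)) {
    dl <- delong_test(scores, comparator$scores, y)
    rep$delong <- c(list(comparator = comparator$name), dl)
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation on n = %d (%d LVH):\n", x$n, x$n_positive))
  cat(sprintf("  AUROC %.3f (%.3f, %.3f)\n", x$auroc, x$auroc_ci[1], x$auroc_ci[2]))
  cat(sprintf("  Youden point: sens %.3f (%.3f, %.3f), spec %.3f (%.3f, %.3f), F1 %.3f\n",
              x$metrics$sensitivity, x$metrics$sensitivity_ci[1], x$metrics$sensitivity_ci[2],
              x$metrics$specificity, x$metrics$specificity_ci[1], x$metrics$specificity_ci[2],
              x$metrics$f1))
  if (!is.null(x$regression)) {
    r <- x$regression
    cat(sprintf("  MAE %.2f (%.2f, %.2f) g/m^2, ME %.2f (%.2f, %.2f), r %.3f, adj R^2 %.3f\n",
                r$mae, r$mae_ci[1], r$mae_ci[2], r$me, r$me_ci[1], r$me_ci[2],
                r$pearson_r, r$adj_r_squared))
  }
  if (!is.null(x$delong)) {
    cat(sprintf("  DeLong vs %s: z %.2f, p %.3g\n", x$delong$comparator,
                x$delong$z, x$delong$p))
  }
  invisible(x)
}
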