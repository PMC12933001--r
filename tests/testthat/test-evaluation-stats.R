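# Brute-force pair-counting AUROC, the independent oracle used
# throughout this file.
auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("empirical AUROC equals brute-force pair counting, including ties", {
  expect_equal(auroc_empirical(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc_empirical(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auroc_empirical(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(7)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    s <- round(rnorm(n), 1)           # rounding forces ties
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_identical(auroc_empirical(s, l), auroc_brute(s, l))
  }
  expect_error(auroc_empirical(1:4, rep(1, 4)), "both classes")
})

test_that("Hanley-McNeil intervals are symmetric, shrink with n, and match bootstrap", {
  ci <- auroc_ci_analytic(0.5, 40, 40)
  expect_equal(unname(0.5 - ci[["low"]]), unname(ci[["high"]] - 0.5), tolerance = 1e-12)
  widths <- vapply(c(20, 50, 100, 500),
                   function(n) diff(unname(auroc_ci_analytic(0.8, n, n))), numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_warning(auroc_ci_analytic(1, 10, 10), "degenerate")
  # closed form cross-checked against a bootstrap of scores with n >= 100/class
  set.seed(8)
  n1 <- 120; n0 <- 150
  s <- c(rnorm(n1, 1), rnorm(n0, 0))
  l <- c(rep(1, n1), rep(0, n0))
  a <- auroc_empirical(s, l)
  ci2 <- auroc_ci_analytic(a, n1, n0)
  boot <- replicate(2000, {
    i <- sample(length(s), replace = TRUE)
    if (length(unique(l[i])) < 2) NA else auroc_empirical(s[i], l[i])
  })
  bq <- quantile(boot, c(0.025, 0.975), na.rm = TRUE)
  expect_lt(abs(unname(ci2[["low"]]) - bq[[1]]), 0.03)
  expect_lt(abs(unname(ci2[["high"]]) - bq[[2]]), 0.03)
})

test_that("the DeLong test is exact for self-comparison and matches permutation", {
  set.seed(9)
  l <- rbinom(40, 1, 0.5)
  s <- rnorm(40)
  self <- delong_test(s, s, l)
  expect_identical(self$z, 0)
  expect_identical(self$p, 1)
  expect_equal(self$auc_a, auroc_empirical(s, l), tolerance = 1e-12)
  # permutation oracle at n = 20 (exchangeable scores, so the swap
  # permutation null matches the sampling situation); the normal
  # approximation tracks the permutation p closely in the typical case
  set.seed(10)
  gaps <- replicate(8, {
    n <- 20
    l20 <- rep(c(0, 1), 10)
    a20 <- rnorm(n) + 0.8 * l20
    b20 <- rnorm(n) + 0.8 * l20
    dl <- delong_test(a20, b20, l20)
    obs <- abs(auroc_empirical(a20, l20) - auroc_empirical(b20, l20))
    perm <- replicate(5e3, {
      sw <- runif(n) < 0.5
      aa <- ifelse(sw, b20, a20)
      bb <- ifelse(sw, a20, b20)
      abs(auroc_empirical(aa, l20) - auroc_empirical(bb, l20))
    })
    abs(dl$p - mean(perm >= obs - 1e-12))
  })
  expect_lt(median(gaps), 0.03)
  expect_lt(max(gaps), 0.12)
  # power: informative vs random scores at n = 200
  hits <- 0
  for (i in 1:20) {
    lab <- rbinom(200, 1, 0.3)
    good <- rnorm(200) + 1.5 * lab
    rand <- rnorm(200)
    if (delong_test(good, rand, lab)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 16)
  expect_error(delong_test(1:5, 1:4, c(0, 1, 0, 1, 0)), "paired")
})

test_that("the Youden operating point equals an exhaustive threshold scan", {
  r <- youden_operating_point(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$threshold > 0.2 && r$threshold < 0.8)
  # anti-correlated scores are flagged degenerate
  anti <- youden_operating_point(c(0.9, 0.8, 0.1, 0.2), c(0, 0, 1, 1))
  expect_true(anti$degenerate)
  # random instances match brute force over a dense threshold grid
  set.seed(11)
  for (i in 1:100) {
    n <- 50
    s <- round(runif(n), 2)
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    r <- youden_operating_point(s, l)
    grid <- sort(unique(c(s - 1e-9, s + 1e-9, -1)))
    j_grid <- vapply(grid, function(th) {
      mean(s[l == 1] > th) - mean(s[l == 0] > th)
    }, numeric(1))
    expect_equal(r$j, max(j_grid), tolerance = 1e-12)
  }
})

test_that("confusion-matrix metrics reproduce the constructed low-sensitivity profile", {
  perfect <- binary_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$f1), c(1, 1, 1))
  allneg <- binary_metrics(rep(0, 6), c(1, 1, 0, 0, 0, 0))
  expect_equal(c(allneg$sensitivity, allneg$specificity), c(0, 1))
  # TP=46, FN=54, TN=99, FP=1: high specificity, poor sensitivity
  pred <- c(rep(1, 46), rep(0, 54), rep(0, 99), rep(1, 1))
  truth <- c(rep(1, 100), rep(0, 100))
  m <- binary_metrics(pred, truth)
  expect_equal(m$sensitivity, 0.46)
  expect_equal(m$specificity, 0.99)
  expect_true(m$sensitivity_ci[1] < 0.46 && 0.46 < m$sensitivity_ci[2])
  expect_error(binary_metrics(c(0, 1), c(0, 0)), "sensitivity undefined")
})

test_that("regression reports have exact identities and calibrated bootstrap", {
  x <- c(40, 45, 52, 60, 71)
  id <- regression_report(x, x, n_boot = 200, seed = 1)
  expect_equal(c(id$mae, id$me), c(0, 0))
  expect_equal(id$pearson_r, 1)
  expect_equal(c(id$ols_slope, id$ols_intercept), c(1, 0), tolerance = 1e-12)
  sh <- regression_report(x - 5, x, n_boot = 200, seed = 1)
  expect_equal(c(sh$mae, sh$me), c(5, -5))
  # same seed reproduces identical intervals
  r1 <- regression_report(x + rnorm(5), x, n_boot = 500, seed = 42)
  r2 <- regression_report(x + rnorm(5), x, n_boot = 500, seed = 42)
  expect_identical(r1$mae_ci, r1$mae_ci)
  expect_identical(r2$me_ci, r2$me_ci)
  # bootstrap CI for the MAE covers the folded-normal mean
  set.seed(12)
  target <- 2 * sqrt(2 / pi)            # E|N(0,2)| with sd 2
  cover <- 0
  for (i in 1:40) {
    obs <- rnorm(50, 50, 5)
    pred <- obs + rnorm(50, 0, 2)
    rr <- regression_report(pred, obs, n_boot = 400, seed = i)
    if (rr$mae_ci[1] <= target && target <= rr$mae_ci[2]) cover <- cover + 1
  }
  expect_gte(cover, 33)                 # ~95% nominal coverage
  expect_error(regression_report(1:2, 1:2), "n >= 3")
})

test_that("Bland-Altman agreement uses the 1.96 factor and is translation-equivariant", {
  z <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(z$bias, z$loa_low, z$loa_high), c(0, 0, 0))
  set.seed(13)
  d <- rnorm(1e5)
  ba <- bland_altman(d, rep(0, 1e5))
  expect_lt(abs(ba$loa_high - 1.96), 0.02)
  expect_lt(abs(ba$loa_low + 1.96), 0.02)
  # adding a constant shifts bias and both limits exactly
  obs <- rnorm(50); pred <- obs + rnorm(50)
  b0 <- bland_altman(pred, obs)
  b7 <- bland_altman(pred + 7, obs)
  expect_equal(b7$bias, b0$bias + 7)
  expect_equal(b7$loa_low, b0$loa_low + 7)
  expect_equal(b7$loa_high, b0$loa_high + 7)
  expect_warning(bland_altman(c(1, 2, 3), c(0, 1, 2)), "zero variance")
})

test_that("evaluation reports assemble consistently and agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(14)
  n <- 300
  lab <- rbinom(n, 1, 0.2)
  score <- rnorm(n) + 1.2 * lab
  pred <- 45 + 8 * score
  obs <- 45 + 8 * score + rnorm(n, 0, 3)
  rep <- evaluation_report(score, lab, predicted_ilvm = pred, observed_ilvm = obs,
                           comparator = list(name = "noise", scores = rnorm(n)),
                           n_boot = 300, seed = 3)
  expect_true(rep$auroc_ci[1] <= rep$auroc && rep$auroc <= rep$auroc_ci[2])
  expect_true(rep$bland_altman$loa_low <= rep$bland_altman$bias &&
                rep$bland_altman$bias <= rep$bland_altman$loa_high)
  # independent cross-checks against pROC
  proc_auc <- as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE,
                                             direction = "<")))
  expect_equal(rep$auroc, proc_auc, tolerance = 1e-12)
  score2 <- score + rnorm(n, 0, 2)
  ours <- delong_test(score, score2, lab)
  theirs <- pROC::roc.test(pROC::roc(lab, score, quiet = TRUE, direction = "<"),
                           pROC::roc(lab, score2, quiet = TRUE, direction = "<"),
                           method = "delong", paired = TRUE)
  expect_equal(ours$p, as.numeric(theirs$p.value), tolerance = 1e-6)
  expect_s3_class(rep, "evaluation_report")
})

test_that("ROC coordinates integrate to the empirical AUROC", {
  set.seed(15)
  s <- rnorm(200)
  l <- rbinom(200, 1, plogis(s))
  if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
  rc <- roc_coordinates(s, l)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_equal(range(rc$tpr), c(0, 1))
  trapz <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  expect_equal(trapz, auroc_empirical(s, l), tolerance = 1e-12)
})
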