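test_that("the pinned architecture has the expected parameter count", {
  cfg <- fcn_config(beat_length = 120)
  model <- build_fcn(cfg, seed = 1)
  # closed-form layer arithmetic, independent of the build:
  # conv: in*k*out + out; BN: 2*out; FC: in*out + out
  expected <- (8 * 8 * 128 + 128 + 2 * 128) +
    (128 * 5 * 256 + 256 + 2 * 256) +
    (256 * 3 * 128 + 128 + 2 * 128) +
    ((128 + 15) * 128 + 128) + (128 * 1 + 1)
  expect_equal(count_parameters(model), expected)
  # metadata inclusion adds exactly metadata_dim * fc_hidden weights
  m0 <- build_fcn(fcn_config(beat_length = 120, metadata_dim = 0), seed = 1)
  expect_equal(count_parameters(model) - count_parameters(m0), 15 * 128)
  # too-short input is a configuration error
  expect_error(fcn_config(beat_length = 6), "receptive field")
})

test_that("log-cosh loss has the correct limits and shape", {
  expect_identical(log_cosh_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(log_cosh_loss(1e-3, 0), (1e-3)^2 / 2, tolerance = 1e-3)
  expect_equal(log_cosh_loss(10, 0), 10 - log(2), tolerance = 1e-6)
  expect_equal(log_cosh_loss(10, 0), log(cosh(10)), tolerance = 1e-9)
  # even in the residual and monotone in |residual|
  set.seed(4)
  for (i in 1:50) {
    r <- rnorm(1, 0, 5)
    expect_equal(log_cosh_loss(r, 0), log_cosh_loss(-r, 0))
    expect_gte(log_cosh_loss(abs(r) + 0.5, 0), log_cosh_loss(abs(r), 0))
  }
  expect_error(log_cosh_loss(1:3, 1:2), "equal length")
})

test_that("the compiled network matches the reference implementation and finite differences", {
  set.seed(11)
  N <- 16; L <- 48
  cfg <- plain_model_config(L)
  model <- build_fcn(cfg, seed = 5)
  x <- array(rnorm(L * 8 * N, 0, 0.5), c(L, 8, N))
  md <- matrix(runif(N * 15), N, 15)
  y <- rnorm(N, 50, 5)
  X <- ecglvh:::flatten_batch(x)
  # inference equivalence
  ref <- ecglvh:::fcn_forward_pass(model, X, md, N, training = FALSE)$output
  cpp <- ecglvh:::cpp_pass(model, x, md, mode = 0L)$pred
  expect_equal(as.numeric(cpp), ref, tolerance = 1e-12)
  # gradient equivalence (training mode, dropout-free)
  fw <- ecglvh:::fcn_forward_pass(model, X, md, N, training = TRUE)
  dz <- tanh(fw$output - y) / N
  bw <- ecglvh:::fcn_backward_pass(fw$model, fw$caches, dz, N)
  cp <- ecglvh:::cpp_pass(model, x, md, y = y, mode = 1L)
  for (g in names(bw$grads)) {
    for (nm in names(bw$grads[[g]])) {
      expect_equal(as.numeric(cp$grads[[g]][[nm]]),
                   as.numeric(bw$grads[[g]][[nm]]),
                   tolerance = 1e-6)
    }
  }
  # finite-difference check on a sample of coordinates
  num_grad <- function(group, name, i, eps = 1e-5) {
    up <- model; up$params[[group]][[name]][i] <- up$params[[group]][[name]][i] + eps
    dn <- model; dn$params[[group]][[name]][i] <- dn$params[[group]][[name]][i] - eps
    (ecglvh:::cpp_pass(up, x, md, y = y, mode = 1L)$loss -
       ecglvh:::cpp_pass(dn, x, md, y = y, mode = 1L)$loss) / (2 * eps)
  }
  for (spec in list(c("conv1", "W", 3), c("conv2", "gamma", 10),
                    c("conv3", "beta", 1), c("fc1", "W", 100), c("fc2", "b", 1))) {
    i <- as.integer(spec[3])
    expect_equal(cp$grads[[spec[1]]][[spec[2]]][i],
                 num_grad(spec[1], spec[2], i),
                 tolerance = 1e-4)
  }
})

test_that("waveform augmentation preserves shape and configured statistics", {
  set.seed(2)
  x <- matrix(rnorm(120 * 8), 120, 8)
  # identity configuration returns the input unchanged
  id_cfg <- finetune_config(crop_max = 0, noise_sd = 0, amp_range = c(1, 1))
  expect_identical(augment_waveform(x, id_cfg), x)
  # output length is invariant over many draws
  cfg <- finetune_config()
  for (i in 1:50) expect_equal(dim(augment_waveform(x, cfg)), dim(x))
  # stated noise level recovered by Monte Carlo on zero input
  zero <- matrix(0, 60, 8)
  ncfg <- finetune_config(crop_max = 0, noise_sd = 0.005, amp_range = c(1, 1))
  draws <- replicate(50, augment_waveform(zero, ncfg))
  expect_equal(sd(draws), 0.005, tolerance = 0.02 * 2)
  expect_error(augment_waveform(matrix(0, 40, 8), finetune_config(crop_max = 25)),
               "too short")
})

test_that("training recovers a planted signal, reduces the rate, and reproduces", {
  fs <- toy_feature_set(n = 200, L = 64, seed = 21)
  tr <- subset_features(fs, 1:150)
  va <- subset_features(fs, 151:200)
  model <- build_fcn(fcn_config(beat_length = 64), seed = 7)
  cfg <- fcn_train_config(max_epochs = 12, lr_reduce_patience = 2,
                          early_stop_patience = 8, seed = 9)
  fit <- train_model(model, tr, va, cfg)
  expect_gte(cor(predict(fit$model, va), va$y), 0.8)
  expect_s3_class(fit$history, "training_history")
  expect_lte(nrow(fit$history$epochs), 12)
  expect_equal(min(fit$history$epochs$val_loss), fit$history$best_val_loss)
  # learning-rate reductions are exact factors of 0.1
  lrs <- unique(fit$history$epochs$lr)
  if (length(lrs) > 1) expect_equal(lrs[2], 5e-5)
  # seeded reproducibility: identical loss traces
  fit2 <- train_model(model, tr, va, cfg)
  expect_identical(fit$history$epochs, fit2$history$epochs)
  # inference determinism and batch-order invariance
  p1 <- predict(fit$model, va)
  expect_identical(p1, predict(fit$model, va))
  perm <- sample(length(va$y))
  expect_equal(predict(fit$model, subset_features(va, perm)), p1[perm],
               tolerance = 1e-6)
})

test_that("a zero-signal cohort trains to chance-level association", {
  fs <- toy_feature_set(n = 300, L = 64, seed = 31, signal = FALSE)
  fs$metadata[] <- 0.5
  tr <- subset_features(fs, 1:200)
  va <- subset_features(fs, 201:250)
  te <- subset_features(fs, 251:300)
  fit <- train_model(build_fcn(fcn_config(beat_length = 64), seed = 3), tr, va,
                     fcn_train_config(max_epochs = 5, seed = 4))
  r <- suppressWarnings(cor(predict(fit$model, te), te$y))
  if (is.na(r)) r <- 0
  expect_lt(abs(r), 0.15)
})

test_that("classification models output calibrated probabilities in (0,1)", {
  fs <- toy_feature_set(n = 120, L = 64, seed = 41)
  fs$y <- as.numeric(fs$y > 50)
  tr <- subset_features(fs, 1:90)
  va <- subset_features(fs, 91:120)
  model <- build_fcn(fcn_config(beat_length = 64, target = "classification"), seed = 2)
  fit <- train_model(model, tr, va, fcn_train_config(max_epochs = 4, seed = 5))
  p <- predict(fit$model, va)
  expect_true(all(p > 0 & p < 1))
})

test_that("metadata inclusion helps when covariates carry signal", {
  fs <- toy_feature_set(n = 240, L = 64, seed = 51, meta_signal = TRUE)
  tr <- subset_features(fs, 1:180)
  va <- subset_features(fs, 181:240)
  cfg <- fcn_train_config(max_epochs = 15, seed = 6)
  with_meta <- train_model(build_fcn(fcn_config(beat_length = 64), seed = 8),
                           tr, va, cfg)
  fs0 <- fs
  no_meta <- train_model(build_fcn(fcn_config(beat_length = 64, metadata_dim = 0),
                                   seed = 8),
                         subset_features(fs0, 1:180), subset_features(fs0, 181:240),
                         cfg)
  expect_lte(with_meta$history$best_val_loss, no_meta$history$best_val_loss)
})

test_that("staged fine-tuning freezes convolutional blocks bit-for-bit in stage 1", {
  fs <- toy_feature_set(n = 160, L = 64, seed = 61)
  tr <- subset_features(fs, 1:120)
  va <- subset_features(fs, 121:160)
  base <- train_model(build_fcn(fcn_config(beat_length = 64), seed = 12), tr, va,
                      fcn_train_config(max_epochs = 6, seed = 13))$model
  # external set: shifted morphology (amplitude scale x 1.5)
  ext <- toy_feature_set(n = 220, L = 64, seed = 62)
  ext$ecg <- ext$ecg * 1.5
  ext_tr <- subset_features(ext, 1:140)
  ext_va <- subset_features(ext, 141:180)
  ext_te <- subset_features(ext, 181:220)

  ft_cfg <- finetune_config(max_epochs_per_stage = 8, early_stop_patience = 8,
                            lr_reduce_patience = 4, seed = 14)
  # stage 1 only: conv weights untouched
  head_only <- base
  head_only$frozen <- c("conv1", "conv2", "conv3")
  stage1 <- train_model(head_only, ext_tr, ext_va,
                        fcn_train_config(learning_rate = ft_cfg$head_lr,
                                         weight_decay = ft_cfg$head_wd,
                                         max_epochs = 3, init_output_bias = FALSE,
                                         seed = 15),
                        augmentation = ft_cfg)$model
  for (blk in c("conv1", "conv2", "conv3")) {
    expect_identical(stage1$params[[blk]], base$params[[blk]])
    expect_identical(stage1$state[[blk]], base$state[[blk]])
  }
  expect_false(identical(stage1$params$fc1$W, base$params$fc1$W))

  # full staged fine-tuning does not hurt held-out error on the shifted set
  ft <- fine_tune(base, ext_tr, ext_va, ft_cfg, augment = TRUE)
  expect_named(ft$history, c("head", "conv3", "conv2", "conv1"))
  mae <- function(m) mean(abs(predict(m, ext_te) - ext_te$y))
  expect_lte(mae(ft$model), mae(base))
  # augmentation disabled also completes with a valid history (smoke)
  ft0 <- fine_tune(base, subset_features(ext, 1:40), subset_features(ext, 41:60),
                   finetune_config(max_epochs_per_stage = 1, seed = 3),
                   augment = FALSE)
  expect_s3_class(ft0$history$head, "training_history")
})

test_that("checkpoints round-trip the model and normalization exactly", {
  fs <- toy_feature_set(n = 40, L = 64, seed = 91)
  model <- build_fcn(fcn_config(beat_length = 64), seed = 9)
  stats <- fit_normalization(metadata_features(toy_profiles(8)))
  path <- withr::local_tempfile(fileext = ".json")
  save_fcn_checkpoint(model, path, normalization = stats)
  back <- load_fcn_checkpoint(path)
  expect_equal(predict(back$model, fs), predict(model, fs), tolerance = 1e-12)
  expect_equal(back$normalization$min, stats$min)
  expect_identical(back$normalization$manifest, stats$manifest)
})
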