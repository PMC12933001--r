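# Fully convolutional network for iLVM regression / LVH classification:
# three convolutional blocks (conv -> batch norm -> ReLU -> max pool),
# dropout, global average pooling, metadata concatenation and two fully
# connected layers. Trained with Adam and a log-cosh loss (regression)
# or binary cross-entropy (classification).

#' FCN architecture configuration
#'
#' The pinned default architecture: three convolutional blocks with
#' (filters, kernel) = (128, 8), (256, 5), (128, 3), batch normalization
#' and max pooling (kernel 2 / stride 2) in each block, dropout 0.4 after
#' the convolutions, global average pooling, concatenation of a 15-entry
#' metadata vector, a 128-unit fully connected layer, dropout 0.6, and a
#' single output (linear for regression over iLVM, sigmoid for direct
#' LVH classification). With the defaults this is ~290k trainable
#' parameters.
#'
#' @param beat_length number of samples per lead fed to the network.
#' @param n_leads number of ECG leads (8).
#' @param metadata_dim length of the metadata vector (15; use 0 for the
#'   ECG-only ablation variant).
#' @param conv_filters,conv_kernels integer vectors of length 3.
#' @param fc_hidden width of the hidden fully connected layer.
#' @param dropout_conv,dropout_fc dropout probabilities in [0, 1).
#' @param target `"regression"` (iLVM, g/m^2) or `"classification"`
#'   (LVH probability).
#' @return object of class `fcn_config`.
#' @export
fcn_config <- function(beat_length, n_leads = 8, metadata_dim = 15,
                       conv_filters = c(128, 256, 128),
                       conv_kernels = c(8, 5, 3), fc_hidden = 128,
                       dropout_conv = 0.4, dropout_fc = 0.6,
                       target = c("regression", "classification")) {
  target <- match.arg(target)
  if (length(conv_filters) != 3 || length(conv_kernels) != 3) {
    stop_invalid("the architecture has exactly 3 convolutional blocks")
  }
  if (any(c(dropout_conv, dropout_fc) < 0) || any(c(dropout_conv, dropout_fc) >= 1)) {
    stop_invalid("dropout probabilities must lie in [0, 1)")
  }
  if (metadata_dim < 0) stop_invalid("metadata_dim must be >= 0")
  L_final <- beat_length
  for (i in 1:3) L_final <- L_final %/% 2L
  if (L_final < 1) {
    stop_invalid("beat_length %d is shorter than the receptive field after pooling",
                 beat_length)
  }
  structure(list(beat_length = as.integer(beat_length), n_leads = as.integer(n_leads),
                 metadata_dim = as.integer(metadata_dim),
                 conv_filters = as.integer(conv_filters),
                 conv_kernels = as.integer(conv_kernels),
                 fc_hidden = as.integer(fc_hidden),
                 dropout_conv = dropout_conv, dropout_fc = dropout_fc,
                 target = target),
            class = "fcn_config")
}

#' Build an FCN model with seeded weight initialisation
#'
#' @param config an [fcn_config()].
#' @param seed integer seed for the He-normal weight initialisation.
#' @return object of class `fcn_model`.
#' @export
build_fcn <- function(config, seed = 1L) {
  stopifnot(inherits(config, "fcn_config"))
  with_seed(seed, {
    params <- list()
    state <- list()
    C <- config$n_leads
    for (blk in 1:3) {
      k <- config$conv_kernels[blk]
      f <- config$conv_filters[blk]
      params[[paste0("conv", blk)]] <- list(
        W = matrix(rnorm(k * C * f, 0, sqrt(2 / (k * C))), nrow = k * C, ncol = f),
        b = numeric(f), gamma = rep(1, f), beta = numeric(f))
      state[[paste0("conv", blk)]] <- list(running_mean = numeric(f),
                                           running_var = rep(1, f))
      C <- f
    }
    d_in <- config$conv_filters[3] + config$metadata_dim
    params$fc1 <- list(W = matrix(rnorm(d_in * config$fc_hidden, 0, sqrt(2 / d_in)),
                                  nrow = d_in, ncol = config$fc_hidden),
                       b = numeric(config$fc_hidden))
    params$fc2 <- list(W = matrix(rnorm(config$fc_hidden, 0, sqrt(1 / config$fc_hidden)),
                                  nrow = config$fc_hidden, ncol = 1),
                       b = 0)
    structure(list(config = config, params = params, state = state,
                   frozen = character(0), seed = as.integer(seed)),
              class = "fcn_model")
  })
}

#' @export
print.fcn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("FCN (%s): blocks (%s) x kernels (%s), fc %d, metadata %d, input %d x %d\n",
              cfg$target, paste(cfg$conv_filters, collapse = ","),
              paste(cfg$conv_kernels, collapse = ","), cfg$fc_hidden,
              cfg$metadata_dim, cfg$beat_length, cfg$n_leads))
  cat(sprintf("  trainable parameters: %d\n", count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums the element counts of all weight, bias and batch-norm scale/shift
#' arrays in groups that are not frozen.
#'
#' @param model an `fcn_model`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "fcn_model"))
  groups <- setdiff(names(model$params), model$frozen)
  sum(vapply(model$params[groups],
             function(g) sum(vapply(g, length, integer(1))), integer(1)))
}

#' Log-cosh loss
#'
#' Mean over samples of log(cosh(predicted - observed)), evaluated in the
#' numerically stable form |x| + log1p(exp(-2|x|)) - log(2). Quadratic
#' (x^2/2) for small residuals, linear (|x| - log 2) for large ones,
#' making training robust to the long-tailed iLVM distribution.
#'
#' @param predicted,observed equal-length numeric vectors (g/m^2).
#' @return non-negative scalar.
#' @export
log_cosh_loss <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop_invalid("predicted and observed must have equal length")
  }
  x <- abs(predicted - observed)
  mean(x + log1p(exp(-2 * x)) - log(2))
}

binary_cross_entropy <- function(prob, label, eps = 1e-12) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(label * log(p) + (1 - label) * log(1 - p))
}

#' Fine-tuning / augmentation configuration
#'
#' Staged unfreezing schedule and morphology-preserving training-set
#' augmentations used when adapting a pre-trained model to an external
#' cohort: random crops of up to `crop_max` samples at each end of all
#' leads followed by linear re-interpolation to the original length,
#' per-lead Gaussian noise (SD 0.005 mV), and a single amplitude scale
#' per beat drawn uniformly from [0.9, 1.1]. The output heads are tuned
#' first (learning rate 5e-5, weight decay 1e-4), then the convolutional
#' blocks one at a time, deepest first (learning rate 1e-4, weight decay
#' 1e-5).
#'
#' @param crop_max maximum crop per end, samples (>= 0).
#' @param noise_sd Gaussian noise SD, mV (>= 0).
#' @param amp_range length-2 ordered amplitude-scaling bounds.
#' @param head_lr,head_wd learning rate / weight decay for the head stage.
#' @param block_lr,block_wd learning rate / weight decay for the
#'   convolutional-block stages.
#' @param max_epochs_per_stage epoch cap per stage.
#' @param early_stop_patience,lr_reduce_patience patience settings reused
#'   from the training loop.
#' @param seed integer seed.
#' @return object of class `finetune_config`.
#' @export
finetune_config <- function(crop_max = 25, noise_sd = 0.005,
                            amp_range = c(0.9, 1.1), head_lr = 5e-5,
                            head_wd = 1e-4, block_lr = 1e-4, block_wd = 1e-5,
                            max_epochs_per_stage = 30,
                            early_stop_patience = 20, lr_reduce_patience = 10,
                            seed = 1L) {
  if (crop_max < 0 || noise_sd < 0) stop_invalid("crop_max and noise_sd must be >= 0")
  if (length(amp_range) != 2 || amp_range[1] > amp_range[2]) {
    stop_invalid("amp_range must be ordered bounds")
  }
  structure(list(crop_max = as.integer(crop_max), noise_sd = noise_sd,
                 amp_range = amp_range, head_lr = head_lr, head_wd = head_wd,
                 block_lr = block_lr, block_wd = block_wd,
                 max_epochs_per_stage = as.integer(max_epochs_per_stage),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 seed = as.integer(seed)),
            class = "finetune_config")
}

#' Augment an ECG beat matrix
#'
#' Applies the augmentations of [finetune_config()] to one beat (L x
#' leads). Uses the current RNG stream; callers seed it.
#'
#' @param x numeric matrix, L samples x leads, mV.
#' @param cfg a `finetune_config`.
#' @return augmented matrix of identical dimensions.
#' @export
augment_waveform <- function(x, cfg) {
  L <- nrow(x)
  if (L <= 2 * cfg$crop_max) stop_invalid("beat too short for crop_max %d", cfg$crop_max)
  c_start <- sample.int(cfg$crop_max + 1L, 1) - 1L
  c_end <- sample.int(cfg$crop_max + 1L, 1) - 1L
  if (c_start + c_end > 0) {
    keep <- (1 + c_start):(L - c_end)
    xs <- seq(1, length(keep), length.out = L)
    x <- apply(x[keep, , drop = FALSE], 2, function(col) approx(seq_along(keep), col, xout = xs)$y)
  }
  if (cfg$noise_sd > 0) x <- x + matrix(rnorm(length(x), 0, cfg$noise_sd), nrow = L)
  scale <- runif(1, cfg$amp_range[1], cfg$amp_range[2])
  x * scale
}

#' Stack per-participant feature vectors into a training tensor
#'
#' @param features list of feature vectors from [build_feature_vector()].
#' @param y numeric targets (iLVM for regression, 0/1 for classification).
#' @param ids optional participant ids.
#' @return object of class `fcn_features`: `ecg` array (L x leads x N),
#'   `metadata` matrix (N x metadata_dim), `y`, `ids`.
#' @export
assemble_feature_set <- function(features, y, ids = NULL) {
  ecg <- simplify2array(lapply(features, `[[`, "ecg"))
  metadata <- do.call(rbind, lapply(features, `[[`, "metadata"))
  structure(list(ecg = ecg, metadata = metadata, y = y, ids = ids),
            class = "fcn_features")
}

#' Subset an `fcn_features` set by index
#'
#' @param fs an `fcn_features` object.
#' @param idx integer or logical index over participants.
#' @return the subsetted `fcn_features`.
#' @export
subset_features <- function(fs, idx) {
  structure(list(ecg = fs$ecg[, , idx, drop = FALSE],
                 metadata = fs$metadata[idx, , drop = FALSE],
                 y = fs$y[idx], ids = fs$ids[idx]),
            class = "fcn_features")
}

# (L, C, N) array -> (L*N, C) matrix with time fastest.
flatten_batch <- function(ecg_arr) {
  d <- dim(ecg_arr)
  m <- aperm(ecg_arr, c(1, 3, 2))
  dim(m) <- c(d[1] * d[3], d[2])
  m
}

#' Training configuration
#'
#' Adam with learning rate 5e-4 and batch size 64; learning rate is
#' reduced by a factor of 0.1 after 10 epochs without validation-loss
#' improvement and training stops after 20 such epochs or `max_epochs`.
#' "Improvement" means a strict decrease of at least `min_delta`. Weights
#' from the best-validation epoch are restored at stop.
#'
#' @param learning_rate initial Adam learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch cap (training always terminates within it).
#' @param early_stop_patience epochs without improvement before stopping.
#' @param lr_reduce_patience epochs without improvement before the
#'   learning-rate reduction.
#' @param lr_reduce_factor multiplicative factor (in (0, 1)).
#' @param weight_decay L2 penalty added to weight gradients (0 during
#'   initial training; fine-tuning sets stage-specific values).
#' @param min_delta minimum decrease counting as improvement.
#' @param init_output_bias initialise the output bias at the median
#'   training target (regression only), so early training fits residual
#'   structure rather than the grand mean.
#' @param seed integer seed controlling shuffling and dropout.
#' @return object of class `train_config`.
#' @export
fcn_train_config <- function(learning_rate = 5e-4, batch_size = 64,
                             max_epochs = 200, early_stop_patience = 20,
                             lr_reduce_patience = 10, lr_reduce_factor = 0.1,
                             weight_decay = 0, min_delta = 1e-6,
                             init_output_bias = TRUE, seed = 1L) {
  if (early_stop_patience <= 0 || lr_reduce_patience <= 0) {
    stop_invalid("patiences must be positive")
  }
  if (lr_reduce_factor <= 0 || lr_reduce_factor >= 1) {
    stop_invalid("lr_reduce_factor must lie in (0, 1)")
  }
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 lr_reduce_factor = lr_reduce_factor,
                 weight_decay = weight_decay, min_delta = min_delta,
                 init_output_bias = isTRUE(init_output_bias),
                 seed = as.integer(seed)),
            class = "train_config")
}

model_loss <- function(model, pred, y) {
  if (model$config$target == "classification") binary_cross_entropy(pred, y)
  else log_cosh_loss(pred, y)
}

# Dispatch one batched pass through the compiled network kernel.
# mode: 0 inference, 1 training step, 2 inference with input gradients.
cpp_pass <- function(model, ecg_arr, metadata, y = numeric(0), mode = 0L,
                     mask_conv = NULL, mask_fc = NULL,
                     bn_train = rep(TRUE, 3), min_block = 1L) {
  cfg <- model$config
  N <- dim(ecg_arr)[3]
  X <- flatten_batch(ecg_arr)
  M <- if (cfg$metadata_dim > 0) metadata else matrix(0, N, 0L)
  cpp_fcn_pass(model$params, model$state, X, M, as.numeric(y),
               cfg$conv_kernels, cfg$beat_length, cfg$n_leads,
               cfg$metadata_dim, cfg$target, as.integer(mode),
               mask_conv, mask_fc, bn_train, as.integer(min_block), 0.1)
}

# Pooled length after the three max-pool layers.
pooled_length <- function(L) {
  for (i in 1:3) L <- L %/% 2L
  L
}

# Inference over a feature set in chunks (avoids huge im2col buffers).
fcn_infer <- function(model, fs, chunk = 256L) {
  N <- dim(fs$ecg)[3]
  out <- numeric(N)
  for (s in seq(1L, N, by = chunk)) {
    idx <- s:min(s + chunk - 1L, N)
    out[idx] <- cpp_pass(model, fs$ecg[, , idx, drop = FALSE],
                         fs$metadata[idx, , drop = FALSE], mode = 0L)$pred
  }
  out
}

#' Train an FCN
#'
#' Mini-batch Adam training with per-epoch validation, learning-rate
#' reduction, early stopping and best-weights restoration; fully
#' reproducible under the config seed. Optional augmentation (a
#' `finetune_config`) is applied to training batches only.
#'
#' @param model an `fcn_model` from [build_fcn()].
#' @param train,validation `fcn_features` sets.
#' @param cfg an [fcn_train_config()].
#' @param augmentation optional [finetune_config()] supplying waveform
#'   augmentation for training batches.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best weights) and `history` (class
#'   `training_history`: per-epoch data.frame plus `best_epoch` and
#'   `stop_reason`).
#' @export
train_model <- function(model, train, validation, cfg = fcn_train_config(),
                        augmentation = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "fcn_model"), inherits(train, "fcn_features"))
  N <- dim(train$ecg)[3]
  if (N < 1 || dim(validation$ecg)[3] < 1) stop_invalid("empty training or validation set")
  if (dim(train$ecg)[1] != model$config$beat_length) {
    stop_invalid("feature beat length %d != model beat_length %d",
                 dim(train$ecg)[1], model$config$beat_length)
  }
  groups <- setdiff(names(model$params), model$frozen)
  if (cfg$init_output_bias && model$config$target == "regression" &&
      !("fc2" %in% model$frozen)) {
    model$params$fc2$b <- median(train$y)
  }
  bn_train <- !(paste0("conv", 1:3) %in% model$frozen)
  min_block <- if (any(bn_train)) min(which(bn_train)) else 4L
  L3 <- pooled_length(model$config$beat_length)
  f3 <- model$config$conv_filters[3]
  fc_h <- model$config$fc_hidden
  p_conv <- model$config$dropout_conv
  p_fc <- model$config$dropout_fc
  with_seed(cfg$seed, {
    opt <- list(t = 0L, state = adam_init(model$params, groups))
    lr <- cfg$learning_rate
    # the incoming weights are the epoch-0 restoration candidate: a run
    # that never improves validation loss leaves the model unchanged
    best_loss <- model_loss(model, fcn_infer(model, validation), validation$y)
    best_params <- model$params
    best_state <- model$state
    best_epoch <- 0L
    since_improve <- 0L
    since_lr <- 0L
    stop_reason <- "max_epochs"
    hist <- vector("list", cfg$max_epochs)

    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(N)
      epoch_loss <- 0
      n_batches <- 0L
      for (s in seq(1L, N, by = cfg$batch_size)) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, N)]
        nb <- length(idx)
        Xarr <- train$ecg[, , idx, drop = FALSE]
        if (!is.null(augmentation)) {
          for (j in seq_len(nb)) {
            Xarr[, , j] <- augment_waveform(Xarr[, , j], augmentation)
          }
        }
        mask_conv <- if (p_conv > 0) {
          matrix((runif(L3 * nb * f3) >= p_conv) / (1 - p_conv), L3 * nb, f3)
        } else NULL
        mask_fc <- if (p_fc > 0) {
          matrix((runif(nb * fc_h) >= p_fc) / (1 - p_fc), nb, fc_h)
        } else NULL
        fw <- cpp_pass(model, Xarr, train$metadata[idx, , drop = FALSE],
                       y = train$y[idx], mode = 1L,
                       mask_conv = mask_conv, mask_fc = mask_fc,
                       bn_train = bn_train, min_block = min_block)
        model$state <- fw$state
        loss <- fw$loss
        if (!is.finite(loss)) {
          stop_invalid("training diverged (non-finite loss) at epoch %d", epoch)
        }
        stepped <- adam_step(model$params, fw$grads, opt, groups, lr,
                             weight_decay = cfg$weight_decay)
        model$params <- stepped$params
        opt <- stepped$opt
        epoch_loss <- epoch_loss + loss
        n_batches <- n_batches + 1L
      }
      val_pred <- fcn_infer(model, validation)
      val_loss <- model_loss(model, val_pred, validation$y)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = epoch_loss / n_batches,
                                  val_loss = val_loss, lr = lr)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                        epoch, epoch_loss / n_batches, val_loss, lr))
      }
      if (val_loss < best_loss - cfg$min_delta) {
        best_loss <- val_loss
        best_params <- model$params
        best_state <- model$state
        best_epoch <- epoch
        since_improve <- 0L
        since_lr <- 0L
      } else {
        since_improve <- since_improve + 1L
        since_lr <- since_lr + 1L
      }
      if (since_improve >= cfg$early_stop_patience) {
        stop_reason <- "early_stop"
        break
      }
      if (since_lr >= cfg$lr_reduce_patience) {
        lr <- lr * cfg$lr_reduce_factor
        since_lr <- 0L
      }
    }
    model$params <- best_params
    model$state <- best_state
    history <- structure(list(epochs = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
                              best_epoch = best_epoch, best_val_loss = best_loss,
                              stop_reason = stop_reason),
                         class = "training_history")
    list(model = model, history = history)
  })
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("Training history: %d epochs, best epoch %d (val loss %.4f), stopped by %s\n",
              nrow(x$epochs), x$best_epoch, x$best_val_loss, x$stop_reason))
  invisible(x)
}

#' Fine-tune a pre-trained FCN on an external cohort
#'
#' Stage 1 trains only the post-GAP head (fully connected layers) with
#' learning rate 5e-5 and weight decay 1e-4, keeping the convolutional
#' blocks frozen bit-for-bit (parameters and normalization statistics).
#' Subsequent stages unfreeze the convolutional blocks one at a time,
#' deepest first, at learning rate 1e-4 / weight decay 1e-5. Training-set
#' augmentation per [finetune_config()] is applied in every stage; each
#' stage uses the usual early-stopping rules.
#'
#' @param model a trained `fcn_model`.
#' @param train,validation `fcn_features` from the external cohort,
#'   preprocessed identically to the original training data.
#' @param cfg a [finetune_config()].
#' @param augment logical; apply waveform augmentation to training
#'   batches.
#' @return list with `model` and `history` (list of per-stage
#'   `training_history` objects, named by stage).
#' @export
fine_tune <- function(model, train, validation, cfg = finetune_config(),
                      augment = TRUE) {
  stopifnot(inherits(model, "fcn_model"), inherits(cfg, "finetune_config"))
  stages <- list(
    list(name = "head", trainable = c("fc1", "fc2"), lr = cfg$head_lr, wd = cfg$head_wd),
    list(name = "conv3", trainable = c("fc1", "fc2", "conv3"), lr = cfg$block_lr, wd = cfg$block_wd),
    list(name = "conv2", trainable = c("fc1", "fc2", "conv3", "conv2"), lr = cfg$block_lr, wd = cfg$block_wd),
    list(name = "conv1", trainable = c("fc1", "fc2", "conv3", "conv2", "conv1"), lr = cfg$block_lr, wd = cfg$block_wd)
  )
  histories <- list()
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    model$frozen <- setdiff(names(model$params), st$trainable)
    tc <- fcn_train_config(learning_rate = st$lr, weight_decay = st$wd,
                           max_epochs = cfg$max_epochs_per_stage,
                           early_stop_patience = cfg$early_stop_patience,
                           lr_reduce_patience = cfg$lr_reduce_patience,
                           init_output_bias = FALSE,
                           seed = derive_seed(cfg$seed, si))
    fit <- train_model(model, train, validation, tc,
                       augmentation = if (augment) cfg else NULL)
    model <- fit$model
    histories[[st$name]] <- fit$history
  }
  model$frozen <- character(0)
  list(model = model, history = histories)
}

#' Save / load an FCN checkpoint
#'
#' Serialises the model (architecture configuration, all parameter
#' arrays, batch-normalization running statistics) and optionally the
#' feature-normalization statistics to a portable JSON file.
#'
#' @param model an `fcn_model`.
#' @param path output file path (`.json`).
#' @param normalization optional `normalization_stats` embedded in the
#'   checkpoint.
#' @return invisibly, `path`.
#' @export
save_fcn_checkpoint <- function(model, path, normalization = NULL) {
  stopifnot(inherits(model, "fcn_model"))
  payload <- list(
    config = unclass(model$config),
    params = lapply(model$params, function(g) lapply(g, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = length(p), data = as.numeric(p))
    })),
    state = model$state, frozen = model$frozen, seed = model$seed,
    normalization = if (!is.null(normalization)) unclass(normalization)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_fcn_checkpoint
#' @return `load_fcn_checkpoint`: list with `model` (an `fcn_model`) and
#'   `normalization` (or NULL).
#' @export
load_fcn_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(fcn_config, payload$config[c("beat_length", "n_leads",
                                              "metadata_dim", "conv_filters",
                                              "conv_kernels", "fc_hidden",
                                              "dropout_conv", "dropout_fc",
                                              "target")])
  params <- lapply(payload$params, function(g) lapply(g, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  }))
  state <- lapply(payload$state, function(s) list(
    running_mean = as.numeric(s$running_mean),
    running_var = as.numeric(s$running_var)))
  model <- structure(list(config = cfg, params = params, state = state,
                          frozen = as.character(payload$frozen %||% character(0)),
                          seed = payload$seed),
                     class = "fcn_model")
  normalization <- NULL
  if (!is.null(payload$normalization)) {
    nz <- payload$normalization
    cont <- as.character(nz$continuous)
    normalization <- structure(
      list(manifest = as.character(nz$manifest), continuous = cont,
           min = setNames(as.numeric(unlist(nz$min)), cont),
           max = setNames(as.numeric(unlist(nz$max)), cont)),
      class = "normalization_stats")
  }
  list(model = model, normalization = normalization)
}

#' Predict with a trained FCN
#'
#' Deterministic inference: dropout off, batch normalization using the
#' stored running statistics. Returns one value per participant (iLVM in
#' g/m^2 for the regression variant, LVH probability for the
#' classification variant).
#'
#' @param object an `fcn_model`.
#' @param features an `fcn_features` set.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.fcn_model <- function(object, features, ...) {
  stopifnot(inherits(features, "fcn_features"))
  if (dim(features$ecg)[1] != object$config$beat_length) {
    stop_invalid("feature beat length %d != model beat_length %d",
                 dim(features$ecg)[1], object$config$beat_length)
  }
  fcn_infer(object, features)
}
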