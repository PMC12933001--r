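# Internal layer engine for the fully convolutional network.
#
# Batched activations are stored as (L*N, F) matrices with the time index
# fastest, so a reshape to array(c(L, N, F)) is free; 1-D convolution is
# im2col + one BLAS matrix multiplication. All layers implement forward
# (with cache) and backward passes; backward also propagates gradients to
# the input so that integrated gradients can reuse the same code path.

# ---- convolution (stride 1, "same" zero padding) ----

conv1d_forward <- function(Xmat, L, N, W, b, k) {
  C <- ncol(Xmat)
  p_l <- (k - 1L) %/% 2L
  Xpad <- array(0, c(L + k - 1L, N, C))
  Xpad[p_l + seq_len(L), , ] <- Xmat
  Xcol <- matrix(0, L * N, k * C)
  for (j in seq_len(k)) {
    Xcol[, (j - 1L) * C + seq_len(C)] <- Xpad[j + 0:(L - 1L), , ]
  }
  Y <- Xcol %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(out = Y, cache = list(Xcol = Xcol, k = k, C = C, L = L, N = N, p_l = p_l))
}

conv1d_backward <- function(dY, cache, W, need_dx = TRUE) {
  k <- cache$k; C <- cache$C; L <- cache$L; N <- cache$N; p_l <- cache$p_l
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dX <- NULL
  if (need_dx) {
    dXcol <- tcrossprod(dY, W)
    dXpad <- array(0, c(L + k - 1L, N, C))
    for (j in seq_len(k)) {
      blk <- dXcol[, (j - 1L) * C + seq_len(C)]
      dim(blk) <- c(L, N, C)
      dXpad[j + 0:(L - 1L), , ] <- dXpad[j + 0:(L - 1L), , ] + blk
    }
    dX <- dXpad[p_l + seq_len(L), , ]
    dim(dX) <- c(L * N, C)
  }
  list(dX = dX, dW = dW, db = db)
}

# Row-broadcast helpers: `v` is a per-column vector recycled down the
# rows without the aperm that sweep() would perform.
sub_col <- function(Y, v) Y - rep(v, each = nrow(Y))
mul_col <- function(Y, v) Y * rep(v, each = nrow(Y))
add_col <- function(Y, v) Y + rep(v, each = nrow(Y))

# ---- batch normalization (per feature map, over batch x time) ----

bn_forward <- function(Y, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(Y)
    v <- colMeans(Y * Y) - mu^2
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * v
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  invstd <- 1 / sqrt(v + eps)
  Yhat <- mul_col(sub_col(Y, mu), invstd)
  out <- add_col(mul_col(Yhat, gamma), beta)
  list(out = out, state = state,
       cache = list(Yhat = Yhat, invstd = invstd, training = training))
}

bn_backward <- function(dOut, cache, gamma) {
  dgamma <- colSums(dOut * cache$Yhat)
  dbeta <- colSums(dOut)
  dYhat <- mul_col(dOut, gamma)
  if (cache$training) {
    t1 <- sub_col(dYhat, colMeans(dYhat))
    t2 <- mul_col(cache$Yhat, colMeans(dYhat * cache$Yhat))
    dY <- mul_col(t1 - t2, cache$invstd)
  } else {
    dY <- mul_col(dYhat, cache$invstd)
  }
  list(dX = dY, dgamma = dgamma, dbeta = dbeta)
}

# ---- ReLU ----

relu_forward <- function(Y) {
  mask <- Y > 0
  list(out = Y * mask, cache = mask)
}

relu_backward <- function(dOut, mask) dOut * mask

# ---- max pooling over time (kernel 2, stride 2) ----

maxpool_forward <- function(Y, L, N) {
  Fdim <- ncol(Y)
  L2 <- L %/% 2L
  arr <- Y
  dim(arr) <- c(L, N, Fdim)
  A <- arr[seq(1L, 2L * L2, 2L), , , drop = FALSE]
  B <- arr[seq(2L, 2L * L2, 2L), , , drop = FALSE]
  take_a <- A >= B
  out <- pmax(A, B)
  dim(out) <- c(L2 * N, Fdim)
  list(out = out, L_out = L2, cache = list(take_a = take_a, L = L, L2 = L2, N = N, Fdim = Fdim))
}

maxpool_backward <- function(dOut, cache) {
  dO <- dOut
  dim(dO) <- c(cache$L2, cache$N, cache$Fdim)
  darr <- array(0, c(cache$L, cache$N, cache$Fdim))
  darr[seq(1L, 2L * cache$L2, 2L), , ] <- dO * cache$take_a
  darr[seq(2L, 2L * cache$L2, 2L), , ] <- dO * !cache$take_a
  dim(darr) <- c(cache$L * cache$N, cache$Fdim)
  darr
}

# ---- global average pooling over time ----

gap_forward <- function(Y, L, N) {
  Fdim <- ncol(Y)
  out <- matrix(colMeans(matrix(Y, nrow = L)), nrow = N, ncol = Fdim)
  list(out = out, cache = list(L = L, N = N, Fdim = Fdim))
}

gap_backward <- function(dOut, cache) {
  matrix(rep(as.numeric(dOut), each = cache$L) / cache$L,
         nrow = cache$L * cache$N, ncol = cache$Fdim)
}

# ---- dropout (inverted scaling) ----

dropout_forward <- function(Y, p, training) {
  if (!training || p <= 0) return(list(out = Y, cache = NULL))
  mask <- matrix((runif(length(Y)) >= p) / (1 - p), nrow = nrow(Y))
  list(out = Y * mask, cache = mask)
}

dropout_backward <- function(dOut, mask) {
  if (is.null(mask)) dOut else dOut * mask
}

# ---- fully connected ----

fc_forward <- function(H, W, b) {
  out <- H %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, cache = H)
}

fc_backward <- function(dOut, H, W) {
  list(dX = tcrossprod(dOut, W), dW = crossprod(H, dOut), db = colSums(dOut))
}

# ---- full network forward/backward ----

# X: (L*N, n_leads) matrix (time fastest); M: (N, metadata_dim) or NULL.
fcn_forward_pass <- function(model, X, M, N, training = FALSE) {
  cfg <- model$config
  caches <- list()
  L <- cfg$beat_length
  cur <- X
  for (blk in 1:3) {
    nm <- paste0("conv", blk)
    p <- model$params[[nm]]
    blk_training <- training && !(nm %in% model$frozen)
    cv <- conv1d_forward(cur, L, N, p$W, p$b, cfg$conv_kernels[blk])
    bn <- bn_forward(cv$out, p$gamma, p$beta, model$state[[nm]], blk_training)
    if (blk_training) model$state[[nm]] <- bn$state
    rl <- relu_forward(bn$out)
    mp <- maxpool_forward(rl$out, L, N)
    caches[[nm]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache, pool = mp$cache)
    cur <- mp$out
    L <- mp$L_out
  }
  dp1 <- dropout_forward(cur, cfg$dropout_conv, training)
  gp <- gap_forward(dp1$out, L, N)
  H <- if (cfg$metadata_dim > 0) cbind(gp$out, M) else gp$out
  f1 <- fc_forward(H, model$params$fc1$W, model$params$fc1$b)
  r1 <- relu_forward(f1$out)
  dp2 <- dropout_forward(r1$out, cfg$dropout_fc, training)
  f2 <- fc_forward(dp2$out, model$params$fc2$W, model$params$fc2$b)
  z <- as.numeric(f2$out)
  out <- if (cfg$target == "classification") 1 / (1 + exp(-z)) else z
  caches$head <- list(dp1 = dp1$cache, gap = gp$cache, fc1 = f1$cache,
                      relu1 = r1$cache, dp2 = dp2$cache, fc2 = f2$cache,
                      z = z, L_final = L)
  list(output = out, caches = caches, model = model)
}

# dz: gradient of the loss w.r.t. the pre-activation output (length N).
# Returns gradients for every parameter group plus the input gradient.
fcn_backward_pass <- function(model, caches, dz, N, need_input_grad = FALSE) {
  cfg <- model$config
  hd <- caches$head
  grads <- list()
  d <- matrix(dz, ncol = 1)
  bk2 <- fc_backward(d, hd$fc2, model$params$fc2$W)
  grads$fc2 <- list(W = bk2$dW, b = bk2$db)
  d <- dropout_backward(bk2$dX, hd$dp2)
  d <- relu_backward(d, hd$relu1)
  bk1 <- fc_backward(d, hd$fc1, model$params$fc1$W)
  grads$fc1 <- list(W = bk1$dW, b = bk1$db)
  dH <- bk1$dX
  nf <- cfg$conv_filters[3]
  dG <- dH[, seq_len(nf), drop = FALSE]
  dM <- if (cfg$metadata_dim > 0) dH[, nf + seq_len(cfg$metadata_dim), drop = FALSE] else NULL
  d <- gap_backward(dG, hd$gap)
  d <- dropout_backward(d, hd$dp1)
  for (blk in 3:1) {
    nm <- paste0("conv", blk)
    cc <- caches[[nm]]
    p <- model$params[[nm]]
    d <- maxpool_backward(d, cc$pool)
    d <- relu_backward(d, cc$relu)
    bn <- bn_backward(d, cc$bn, p$gamma)
    cv <- conv1d_backward(bn$dX, cc$conv, p$W,
                          need_dx = blk > 1 || need_input_grad)
    grads[[nm]] <- list(W = cv$dW, b = cv$db, gamma = bn$dgamma, beta = bn$dbeta)
    if (blk > 1 || need_input_grad) d <- cv$dX
  }
  list(grads = grads, dX = if (need_input_grad) d else NULL, dM = dM)
}

# ---- Adam optimiser ----

adam_init <- function(params, groups) {
  st <- list()
  for (g in groups) {
    st[[g]] <- lapply(params[[g]], function(p) list(m = p * 0, v = p * 0))
  }
  st
}

adam_step <- function(params, grads, opt, groups, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (g in groups) {
    for (nm in names(grads[[g]])) {
      gr <- grads[[g]][[nm]]
      if (weight_decay > 0 && nm == "W") gr <- gr + weight_decay * params[[g]][[nm]]
      s <- opt$state[[g]][[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * gr
      s$v <- beta2 * s$v + (1 - beta2) * gr * gr
      opt$state[[g]][[nm]] <- s
      params[[g]][[nm]] <- params[[g]][[nm]] -
        lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
    }
  }
  list(params = params, opt = opt)
}
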