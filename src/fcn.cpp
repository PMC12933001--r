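// Fused forward/backward pass of the fully convolutional network.
//
// Activation layout matches the R reference implementation in
// R/fcn_layers.R: batched activations are (L*N, F) matrices with the
// time index fastest, convolutions are im2col + GEMM, batch
// normalization runs per feature map over batch x time. Dropout masks
// are generated in R (keeping all randomness in R's seeded RNG) and
// passed in pre-scaled by 1/(1-p).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct ConvCache {
  mat Xcol;
  int L, N, C, k, p_l;
};

struct BnCache {
  mat Yhat;
  rowvec invstd;
  bool training;
};

struct PoolCache {
  umat take_a;   // (L2*N, F): 1 when the first element of the pair won
  int L, L2, N;
};

static mat conv_forward(const mat& Xmat, int L, int N, const mat& W,
                        const rowvec& b, int k, ConvCache& cc) {
  const int C = Xmat.n_cols;
  const int p_l = (k - 1) / 2;
  cc.L = L; cc.N = N; cc.C = C; cc.k = k; cc.p_l = p_l;
  cc.Xcol.set_size(L * N, k * C);
  // padded time axis per (channel, sample) column
  for (int c = 0; c < C; ++c) {
    // view the channel as (L, N)
    const double* src = Xmat.colptr(c);
    for (int j = 0; j < k; ++j) {
      double* dst = cc.Xcol.colptr(j * C + c);
      const int off = j - p_l;  // source time offset for output t: t + off
      for (int n = 0; n < N; ++n) {
        const double* s = src + (size_t)n * L;
        double* d = dst + (size_t)n * L;
        const int t0 = std::max(0, -off);
        const int t1 = std::min(L, L - off);
        for (int t = 0; t < t0; ++t) d[t] = 0.0;
        for (int t = t0; t < t1; ++t) d[t] = s[t + off];
        for (int t = t1; t < L; ++t) d[t] = 0.0;
      }
    }
  }
  mat Y = cc.Xcol * W;
  Y.each_row() += b;
  return Y;
}

static mat conv_backward(const mat& dY, const ConvCache& cc, const mat& W,
                         mat& dW, rowvec& db, bool need_dx) {
  dW = cc.Xcol.t() * dY;
  db = sum(dY, 0);
  mat dX;
  if (need_dx) {
    mat dXcol = dY * W.t();
    dX.zeros(cc.L * cc.N, cc.C);
    for (int c = 0; c < cc.C; ++c) {
      double* dst = dX.colptr(c);
      for (int j = 0; j < cc.k; ++j) {
        const double* src = dXcol.colptr(j * cc.C + c);
        const int off = j - cc.p_l;
        for (int n = 0; n < cc.N; ++n) {
          const double* s = src + (size_t)n * cc.L;
          double* d = dst + (size_t)n * cc.L;
          const int t0 = std::max(0, -off);
          const int t1 = std::min(cc.L, cc.L - off);
          for (int t = t0; t < t1; ++t) d[t + off] += s[t];
        }
      }
    }
  }
  return dX;
}

static mat bn_forward(const mat& Y, const rowvec& gamma, const rowvec& beta,
                      rowvec& run_mean, rowvec& run_var, bool training,
                      double momentum, double eps, BnCache& bc) {
  rowvec mu, v;
  if (training) {
    mu = mean(Y, 0);
    v = mean(square(Y), 0) - square(mu);
    run_mean = (1.0 - momentum) * run_mean + momentum * mu;
    run_var = (1.0 - momentum) * run_var + momentum * v;
  } else {
    mu = run_mean;
    v = run_var;
  }
  bc.invstd = 1.0 / sqrt(v + eps);
  bc.training = training;
  bc.Yhat = Y;
  bc.Yhat.each_row() -= mu;
  bc.Yhat.each_row() %= bc.invstd;
  mat out = bc.Yhat;
  out.each_row() %= gamma;
  out.each_row() += beta;
  return out;
}

static mat bn_backward(const mat& dOut, const BnCache& bc, const rowvec& gamma,
                       rowvec& dgamma, rowvec& dbeta) {
  dgamma = sum(dOut % bc.Yhat, 0);
  dbeta = sum(dOut, 0);
  mat dYhat = dOut;
  dYhat.each_row() %= gamma;
  mat dY;
  if (bc.training) {
    rowvec m1 = mean(dYhat, 0);
    rowvec m2 = mean(dYhat % bc.Yhat, 0);
    dY = dYhat;
    dY.each_row() -= m1;
    mat t2 = bc.Yhat;
    t2.each_row() %= m2;
    dY -= t2;
    dY.each_row() %= bc.invstd;
  } else {
    dY = dYhat;
    dY.each_row() %= bc.invstd;
  }
  return dY;
}

static mat maxpool_forward(const mat& Y, int L, int N, PoolCache& pc) {
  const int F = Y.n_cols;
  const int L2 = L / 2;
  pc.L = L; pc.L2 = L2; pc.N = N;
  mat out(L2 * N, F);
  pc.take_a.set_size(L2 * N, F);
  for (int f = 0; f < F; ++f) {
    const double* src = Y.colptr(f);
    double* dst = out.colptr(f);
    uword* tk = pc.take_a.colptr(f);
    for (int n = 0; n < N; ++n) {
      const double* s = src + (size_t)n * L;
      double* d = dst + (size_t)n * L2;
      uword* t = tk + (size_t)n * L2;
      for (int i = 0; i < L2; ++i) {
        const double x1 = s[2 * i], x2 = s[2 * i + 1];
        if (x1 >= x2) { d[i] = x1; t[i] = 1; } else { d[i] = x2; t[i] = 0; }
      }
    }
  }
  return out;
}

static mat maxpool_backward(const mat& dOut, const PoolCache& pc) {
  const int F = dOut.n_cols;
  mat dY(pc.L * pc.N, F, fill::zeros);
  for (int f = 0; f < F; ++f) {
    const double* src = dOut.colptr(f);
    const uword* tk = pc.take_a.colptr(f);
    double* dst = dY.colptr(f);
    for (int n = 0; n < pc.N; ++n) {
      const double* s = src + (size_t)n * pc.L2;
      const uword* t = tk + (size_t)n * pc.L2;
      double* d = dst + (size_t)n * pc.L;
      for (int i = 0; i < pc.L2; ++i) {
        d[2 * i + (t[i] ? 0 : 1)] = s[i];
      }
    }
  }
  return dY;
}

static mat gap_forward(const mat& Y, int L, int N) {
  const int F = Y.n_cols;
  mat out(N, F);
  for (int f = 0; f < F; ++f) {
    const double* src = Y.colptr(f);
    double* dst = out.colptr(f);
    for (int n = 0; n < N; ++n) {
      double s = 0;
      const double* p = src + (size_t)n * L;
      for (int t = 0; t < L; ++t) s += p[t];
      dst[n] = s / L;
    }
  }
  return out;
}

static mat gap_backward(const mat& dOut, int L, int N) {
  const int F = dOut.n_cols;
  mat dY(L * N, F);
  for (int f = 0; f < F; ++f) {
    const double* src = dOut.colptr(f);
    double* dst = dY.colptr(f);
    for (int n = 0; n < N; ++n) {
      const double g = src[n] / L;
      double* p = dst + (size_t)n * L;
      for (int t = 0; t < L; ++t) p[t] = g;
    }
  }
  return dY;
}

struct BlockParams {
  mat W; rowvec b; rowvec gamma; rowvec beta;
  rowvec run_mean; rowvec run_var;
  int k;
};

static void read_params(const Rcpp::List& params, const Rcpp::List& state,
                        const Rcpp::IntegerVector& kernels,
                        std::vector<BlockParams>& blocks,
                        mat& W1, rowvec& b1, mat& W2, double& b2) {
  for (int i = 0; i < 3; ++i) {
    Rcpp::List p = params[i];
    Rcpp::List st = state[i];
    BlockParams bp;
    bp.W = Rcpp::as<mat>(p["W"]);
    bp.b = Rcpp::as<rowvec>(p["b"]);
    bp.gamma = Rcpp::as<rowvec>(p["gamma"]);
    bp.beta = Rcpp::as<rowvec>(p["beta"]);
    bp.run_mean = Rcpp::as<rowvec>(st["running_mean"]);
    bp.run_var = Rcpp::as<rowvec>(st["running_var"]);
    bp.k = kernels[i];
    blocks.push_back(bp);
  }
  Rcpp::List f1 = params[3], f2 = params[4];
  W1 = Rcpp::as<mat>(f1["W"]);
  b1 = Rcpp::as<rowvec>(f1["b"]);
  W2 = Rcpp::as<mat>(f2["W"]);
  b2 = Rcpp::as<Rcpp::NumericVector>(f2["b"])[0];
}

// Full pass. mode: 0 = inference (returns predictions only), 1 = training
// step (returns loss, predictions, gradients, updated BN state),
// 2 = inference with input gradients (for integrated gradients).
// [[Rcpp::export]]
Rcpp::List cpp_fcn_pass(Rcpp::List params, Rcpp::List state,
                        Rcpp::NumericVector x, Rcpp::NumericMatrix meta,
                        Rcpp::NumericVector y,
                        Rcpp::IntegerVector kernels, int L, int n_leads,
                        int metadata_dim, std::string target, int mode,
                        Rcpp::Nullable<Rcpp::NumericMatrix> mask_conv,
                        Rcpp::Nullable<Rcpp::NumericMatrix> mask_fc,
                        Rcpp::LogicalVector bn_train, int min_block,
                        double momentum) {
  const int N = meta.nrow() > 0 ? meta.nrow() : (int)(x.size() / ((size_t)L * n_leads));
  std::vector<BlockParams> blocks;
  mat W1; rowvec b1; mat W2; double b2;
  read_params(params, state, kernels, blocks, W1, b1, W2, b2);
  const bool training = (mode == 1);
  const bool use_meta = metadata_dim > 0;

  mat cur((double*)x.begin(), (size_t)L * N, n_leads);  // (L*N, C), copy-free view
  mat curY = cur;  // working copy
  std::vector<ConvCache> ccs(3);
  std::vector<BnCache> bcs(3);
  std::vector<PoolCache> pcs(3);
  std::vector<mat> relu_mask(3);
  int Lc = L;
  for (int i = 0; i < 3; ++i) {
    bool blk_train = training && bn_train[i];
    mat Yc = conv_forward(curY, Lc, N, blocks[i].W, blocks[i].b, blocks[i].k, ccs[i]);
    mat Yb = bn_forward(Yc, blocks[i].gamma, blocks[i].beta,
                        blocks[i].run_mean, blocks[i].run_var,
                        blk_train, momentum, 1e-5, bcs[i]);
    relu_mask[i] = conv_to<mat>::from(Yb > 0);
    Yb %= relu_mask[i];
    curY = maxpool_forward(Yb, Lc, N, pcs[i]);
    Lc /= 2;
  }
  mat dmask_conv;
  if (training && mask_conv.isNotNull()) {
    dmask_conv = Rcpp::as<mat>(mask_conv.get());
    curY %= dmask_conv;
  }
  mat G = gap_forward(curY, Lc, N);
  mat H = use_meta ? join_rows(G, Rcpp::as<mat>(meta)) : G;
  mat A1 = H * W1;
  A1.each_row() += b1;
  mat r1 = conv_to<mat>::from(A1 > 0);
  mat Z1 = A1 % r1;
  mat dmask_fc;
  if (training && mask_fc.isNotNull()) {
    dmask_fc = Rcpp::as<mat>(mask_fc.get());
    Z1 %= dmask_fc;
  }
  vec z = Z1 * W2 + b2;
  vec pred = z;
  if (target == "classification") pred = 1.0 / (1.0 + exp(-z));

  if (mode == 0) {
    return Rcpp::List::create(Rcpp::Named("pred") = pred);
  }

  // ---- loss gradient w.r.t. z ----
  vec dz(N);
  double loss = 0.0;
  if (mode == 1) {
    const vec yy = Rcpp::as<vec>(y);
    if (target == "classification") {
      const double eps = 1e-12;
      vec p = clamp(pred, eps, 1.0 - eps);
      loss = -mean(yy % log(p) + (1.0 - yy) % log(1.0 - p));
      dz = (pred - yy) / N;
    } else {
      vec r = abs(pred - yy);
      loss = mean(r + log1p(exp(-2.0 * r)) - std::log(2.0));
      dz = tanh(pred - yy) / N;
    }
  } else {
    // mode 2: gradient of the (per-sample) model output
    if (target == "classification") dz = pred % (1.0 - pred);
    else dz.ones();
  }

  // ---- backward ----
  mat dZ1 = dz * W2.t();            // (N, fc_hidden)
  mat dW2 = Z1.t() * dz;
  double db2 = accu(dz);
  if (training && mask_fc.isNotNull()) dZ1 %= dmask_fc;
  dZ1 %= r1;
  mat dW1 = H.t() * dZ1;
  rowvec db1 = sum(dZ1, 0);
  mat dH = dZ1 * W1.t();
  mat dG = dH.cols(0, G.n_cols - 1);
  mat dM;
  if (use_meta) dM = dH.cols(G.n_cols, dH.n_cols - 1);
  mat d = gap_backward(dG, Lc, N);
  if (training && mask_conv.isNotNull()) d %= dmask_conv;

  Rcpp::List grads(3);
  const bool need_input_grad = (mode == 2);
  const int stop_block = need_input_grad ? 1 : min_block;
  for (int i = 2; i >= 0; --i) {
    if (i + 1 < stop_block) break;
    d = maxpool_backward(d, pcs[i]);
    d %= relu_mask[i];
    rowvec dgamma, dbeta;
    d = bn_backward(d, bcs[i], blocks[i].gamma, dgamma, dbeta);
    mat dW; rowvec db;
    const bool need_dx = (i > 0 && i + 1 > stop_block) || (i == 0 && need_input_grad);
    mat dX = conv_backward(d, ccs[i], blocks[i].W, dW, db, need_dx);
    grads[i] = Rcpp::List::create(Rcpp::Named("W") = dW,
                                  Rcpp::Named("b") = db,
                                  Rcpp::Named("gamma") = dgamma,
                                  Rcpp::Named("beta") = dbeta);
    if (need_dx) d = dX; else break;
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("pred") = pred,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("conv1") = grads[0], Rcpp::Named("conv2") = grads[1],
      Rcpp::Named("conv3") = grads[2],
      Rcpp::Named("fc1") = Rcpp::List::create(Rcpp::Named("W") = dW1,
                                              Rcpp::Named("b") = db1),
      Rcpp::Named("fc2") = Rcpp::List::create(Rcpp::Named("W") = dW2,
                                              Rcpp::Named("b") = db2)),
    Rcpp::Named("state") = Rcpp::List::create(
      Rcpp::Named("conv1") = Rcpp::List::create(
        Rcpp::Named("running_mean") = blocks[0].run_mean,
        Rcpp::Named("running_var") = blocks[0].run_var),
      Rcpp::Named("conv2") = Rcpp::List::create(
        Rcpp::Named("running_mean") = blocks[1].run_mean,
        Rcpp::Named("running_var") = blocks[1].run_var),
      Rcpp::Named("conv3") = Rcpp::List::create(
        Rcpp::Named("running_mean") = blocks[2].run_mean,
        Rcpp::Named("running_var") = blocks[2].run_var)));
  if (need_input_grad) {
    out["d_input"] = d;   // (L*N, C)
    if (use_meta) out["d_metadata"] = dM;
  }
  return out;
}
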