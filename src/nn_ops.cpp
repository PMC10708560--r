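// Dense-algebra kernels for the temporal network layers.
//
// Tensor layout convention: a batch of sequences is an arma::cube with
// dimensions (time, channels, batch); slice b is the (T x C) matrix of
// sample b.  Convolution weights are a cube (kernel, in_ch, out_ch);
// LSTM gate order is [i | f | g | o] in blocks of `units` columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static std::vector<mat> kernel_mats(const cube& W) {
  // W(k, cin, cout) -> K matrices of shape (cin x cout)
  const uword K = W.n_rows, Cin = W.n_cols, Cout = W.n_slices;
  std::vector<mat> Wk(K);
  for (uword k = 0; k < K; ++k) {
    mat m(Cin, Cout);
    for (uword o = 0; o < Cout; ++o) m.col(o) = W.slice(o).row(k).t();
    Wk[k] = m;
  }
  return Wk;
}

// im2col matrix over the whole batch: row t + Tout*s, column cin*K + k
// holds x_s(t + k*d - shift, cin), zero outside bounds (causal padding).
static mat im2col_batch(const cube& X, int K, int dilation, int Tout,
                        int shift) {
  const int T = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  mat M(Tout * B, K * Cin, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    for (int cin = 0; cin < Cin; ++cin) {
      for (int k = 0; k < K; ++k) {
        const int off = k * dilation - shift;
        const int t0 = std::max(0, -off);
        const int t1 = std::min(Tout - 1, T - 1 - off);
        if (t0 > t1) continue;
        M(span(s * Tout + t0, s * Tout + t1), span(cin * K + k)) =
            Xs(span(t0 + off, t1 + off), span(cin));
      }
    }
  }
  return M;
}

static mat weight_mat(const cube& W) {
  const int K = W.n_rows, Cin = W.n_cols, Cout = W.n_slices;
  mat Wm(K * Cin, Cout);
  for (int o = 0; o < Cout; ++o) Wm.col(o) = vectorise(W.slice(o));
  return Wm;
}

// single batched GEMM is worth the im2col copy up to this working-set size
static bool use_gemm_path(double Tout, double B, double K, double Cin) {
  return Tout * B * K * Cin <= 3e7;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_fw(const arma::cube& X, const arma::cube& W,
                         const arma::vec& b, int dilation, bool causal) {
  const int T = X.n_rows, B = X.n_slices;
  const int K = W.n_rows, Cin = W.n_cols, Cout = W.n_slices;
  const int span_ = (K - 1) * dilation;
  const int Tout = causal ? T : T - span_;
  if (Tout < 1) Rcpp::stop("input shorter than the receptive span of the kernel");
  cube Y(Tout, Cout, B, fill::zeros);
  if (use_gemm_path(Tout, B, K, Cin)) {
    mat M = im2col_batch(X, K, dilation, Tout, causal ? span_ : 0);
    mat Ycat = M * weight_mat(W);
    Ycat.each_row() += b.t();
    for (int s = 0; s < B; ++s)
      Y.slice(s) = Ycat.rows(s * Tout, (s + 1) * Tout - 1);
    return Y;
  }
  std::vector<mat> Wk = kernel_mats(W);
  for (int s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    mat& Ys = Y.slice(s);
    for (int k = 0; k < K; ++k) {
      const int off = k * dilation;
      if (causal) {
        // tap k reads x[t - span + k*d]; zero left padding is implicit
        const int start = span_ - off;
        if (start <= T - 1)
          Ys.rows(start, T - 1) += Xs.rows(0, T - 1 - start) * Wk[k];
      } else {
        Ys += Xs.rows(off, off + Tout - 1) * Wk[k];
      }
    }
    Ys.each_row() += b.t();
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bw(const arma::cube& X, const arma::cube& W,
                         const arma::cube& dY, int dilation, bool causal) {
  const int T = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const int K = W.n_rows, Cout = W.n_slices;
  const int span_ = (K - 1) * dilation;
  const int Tout = causal ? T : T - span_;
  cube dX(T, Cin, B, fill::zeros);
  cube dW(K, Cin, Cout, fill::zeros);
  vec db(Cout, fill::zeros);
  if (use_gemm_path(Tout, B, K, Cin)) {
    const int shift = causal ? span_ : 0;
    mat M = im2col_batch(X, K, dilation, Tout, shift);
    mat dYcat(Tout * B, Cout);
    for (int s = 0; s < B; ++s)
      dYcat.rows(s * Tout, (s + 1) * Tout - 1) = dY.slice(s);
    mat Wm = weight_mat(W);
    mat dWm = M.t() * dYcat;
    for (int o = 0; o < Cout; ++o)
      dW.slice(o) = reshape(dWm.col(o), K, Cin);
    db = sum(dYcat, 0).t();
    mat dM = dYcat * Wm.t();
    for (int s = 0; s < B; ++s) {
      mat& dXs = dX.slice(s);
      for (int cin = 0; cin < Cin; ++cin) {
        for (int k = 0; k < K; ++k) {
          const int off = k * dilation - shift;
          const int t0 = std::max(0, -off);
          const int t1 = std::min(Tout - 1, T - 1 - off);
          if (t0 > t1) continue;
          dXs(span(t0 + off, t1 + off), span(cin)) +=
              dM(span(s * Tout + t0, s * Tout + t1), span(cin * K + k));
        }
      }
    }
    return Rcpp::List::create(Rcpp::Named("dx") = dX,
                              Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db);
  }
  std::vector<mat> Wk = kernel_mats(W);
  std::vector<mat> dWk(K, mat(Cin, Cout, fill::zeros));
  for (int s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    const mat& dYs = dY.slice(s);
    mat& dXs = dX.slice(s);
    for (int k = 0; k < K; ++k) {
      const int off = k * dilation;
      if (causal) {
        const int start = span_ - off;
        if (start <= T - 1) {
          dXs.rows(0, T - 1 - start) += dYs.rows(start, T - 1) * Wk[k].t();
          dWk[k] += Xs.rows(0, T - 1 - start).t() * dYs.rows(start, T - 1);
        }
      } else {
        dXs.rows(off, off + Tout - 1) += dYs * Wk[k].t();
        dWk[k] += Xs.rows(off, off + Tout - 1).t() * dYs;
      }
    }
    db += sum(dYs, 0).t();
  }
  for (int k = 0; k < K; ++k)
    for (int o = 0; o < Cout; ++o)
      dW.slice(o).row(k) = dWk[k].col(o).t();
  return Rcpp::List::create(Rcpp::Named("dx") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool1d_fw(const arma::cube& X, int pool) {
  const int T = X.n_rows, C = X.n_cols, B = X.n_slices;
  const int Tout = T / pool;
  if (Tout < 1) Rcpp::stop("input shorter than the pooling window");
  cube Y(Tout, C, B);
  ucube idx(Tout, C, B);  // time index (0-based) of the winning element
  for (int s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    for (int c = 0; c < C; ++c) {
      for (int t = 0; t < Tout; ++t) {
        const int t0 = t * pool;
        uword which = t0;
        double best = Xs(t0, c);
        for (int k = 1; k < pool; ++k) {
          if (Xs(t0 + k, c) > best) { best = Xs(t0 + k, c); which = t0 + k; }
        }
        Y(t, c, s) = best;
        idx(t, c, s) = which;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool1d_bw(const arma::ucube& idx, const arma::cube& dY,
                            int T) {
  const int Tout = dY.n_rows, C = dY.n_cols, B = dY.n_slices;
  cube dX(T, C, B, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < Tout; ++t)
        dX(idx(t, c, s), c, s) += dY(t, c, s);
  return dX;
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static mat time_slice(const cube& X, int t) {
  const int C = X.n_cols, B = X.n_slices;
  mat M(B, C);
  for (int s = 0; s < B; ++s) M.row(s) = X.slice(s).row(t);
  return M;
}

// Single-direction LSTM over the whole batch, returning the full hidden
// sequence plus the per-step activations needed by the backward pass.
// reverse=true processes time back-to-front (outputs stay aligned to input
// positions), which is how the backward half of a Bi-LSTM runs.
// The input projection X*Wx is hoisted out of the recurrence and done as
// one (T x Cin)(Cin x 4H) matmul per record.
// [[Rcpp::export]]
Rcpp::List cpp_lstm_fw(const arma::cube& X, const arma::mat& Wx,
                       const arma::mat& Wh, const arma::vec& b, bool reverse) {
  const int T = X.n_rows, B = X.n_slices;
  const int H = Wh.n_rows;
  cube Hseq(T, H, B, fill::zeros);
  // caches, laid out (B, H, T)
  cube Gi(B, H, T), Gf(B, H, T), Gg(B, H, T), Go(B, H, T), Cst(B, H, T);
  cube XW(T, 4 * H, B);
  for (int s = 0; s < B; ++s) {
    XW.slice(s) = X.slice(s) * Wx;
    XW.slice(s).each_row() += b.t();
  }
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  mat Z(B, 4 * H);
  for (int step = 0; step < T; ++step) {
    const int t = reverse ? (T - 1 - step) : step;
    for (int s = 0; s < B; ++s) Z.row(s) = XW.slice(s).row(t);
    Z += h * Wh;
    mat i = sigm(Z.cols(0, H - 1));
    mat f = sigm(Z.cols(H, 2 * H - 1));
    mat g = tanh(Z.cols(2 * H, 3 * H - 1));
    mat o = sigm(Z.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    Gi.slice(t) = i; Gf.slice(t) = f; Gg.slice(t) = g; Go.slice(t) = o;
    Cst.slice(t) = c;
    for (int s = 0; s < B; ++s) Hseq.slice(s).row(t) = h.row(s);
  }
  return Rcpp::List::create(
      Rcpp::Named("h") = Hseq, Rcpp::Named("i") = Gi, Rcpp::Named("f") = Gf,
      Rcpp::Named("g") = Gg, Rcpp::Named("o") = Go, Rcpp::Named("c") = Cst);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_bw(const arma::cube& X, const arma::mat& Wx,
                       const arma::mat& Wh, const arma::cube& dH,
                       const arma::cube& Gi, const arma::cube& Gf,
                       const arma::cube& Gg, const arma::cube& Go,
                       const arma::cube& Cst, bool reverse) {
  const int T = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const int H = Wh.n_rows;
  mat dWx(Cin, 4 * H, fill::zeros), dWh(H, 4 * H, fill::zeros);
  vec db(4 * H, fill::zeros);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  cube dZall(B, 4 * H, T);  // pre-activation grads, scattered back at the end
  for (int step = T - 1; step >= 0; --step) {
    const int t = reverse ? (T - 1 - step) : step;
    const int tprev = reverse ? (t + 1) : (t - 1);
    const bool has_prev = reverse ? (tprev <= T - 1) : (tprev >= 0);
    mat dh = time_slice(dH, t) + dh_next;
    const mat& i = Gi.slice(t); const mat& f = Gf.slice(t);
    const mat& g = Gg.slice(t); const mat& o = Go.slice(t);
    mat tc = tanh(Cst.slice(t));
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat cprev(B, H, fill::zeros), hprev(B, H, fill::zeros);
    if (has_prev) {
      cprev = Cst.slice(tprev);
      hprev = Go.slice(tprev) % tanh(cprev);
    }
    mat& dZ = dZall.slice(t);
    dZ.cols(0, H - 1) = (dc % g) % i % (1.0 - i);
    dZ.cols(H, 2 * H - 1) = (dc % cprev) % f % (1.0 - f);
    dZ.cols(2 * H, 3 * H - 1) = (dc % i) % (1.0 - g % g);
    dZ.cols(3 * H, 4 * H - 1) = (dh % tc) % o % (1.0 - o);
    dWh += hprev.t() * dZ;
    dh_next = dZ * Wh.t();
    dc_next = dc % f;
  }
  // batched input-side gradients: one pair of matmuls per record
  cube dX(T, Cin, B, fill::zeros);
  mat dZs(T, 4 * H);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < T; ++t) dZs.row(t) = dZall.slice(t).row(s);
    dX.slice(s) = dZs * Wx.t();
    dWx += X.slice(s).t() * dZs;
    db += sum(dZs, 0).t();
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX, Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db);
}

// ---- channel-wise reductions for batch normalization over (T, C, B) ----

// [[Rcpp::export]]
arma::vec cpp_chan_sum(const arma::cube& X) {
  vec out(X.n_cols, fill::zeros);
  for (uword s = 0; s < X.n_slices; ++s)
    out += sum(X.slice(s), 0).t();
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_chan_dot(const arma::cube& X, const arma::cube& Y) {
  vec out(X.n_cols, fill::zeros);
  for (uword s = 0; s < X.n_slices; ++s)
    out += sum(X.slice(s) % Y.slice(s), 0).t();
  return out;
}

// y[t,c,b] = x[t,c,b] * a[c] + b[c]
// [[Rcpp::export]]
arma::cube cpp_chan_affine(const arma::cube& X, const arma::vec& a,
                           const arma::vec& b) {
  cube Y(X.n_rows, X.n_cols, X.n_slices);
  for (uword s = 0; s < X.n_slices; ++s) {
    Y.slice(s) = X.slice(s);
    Y.slice(s).each_row() %= a.t();
    Y.slice(s).each_row() += b.t();
  }
  return Y;
}

// dx = inv_sd[c] * (dxhat - m1[c] - xhat * m2[c])
// [[Rcpp::export]]
arma::cube cpp_bn_bw_dx(const arma::cube& dxhat, const arma::cube& xhat,
                        const arma::vec& m1, const arma::vec& m2,
                        const arma::vec& inv_sd) {
  cube dX(dxhat.n_rows, dxhat.n_cols, dxhat.n_slices);
  for (uword s = 0; s < dxhat.n_slices; ++s) {
    mat m = dxhat.slice(s);
    m.each_row() -= m1.t();
    mat xm = xhat.slice(s);
    xm.each_row() %= m2.t();
    m -= xm;
    m.each_row() %= inv_sd.t();
    dX.slice(s) = m;
  }
  return dX;
}

// fused batch-norm forward: xhat = (x - mu) * inv_sd, y = gamma * xhat + beta
// [[Rcpp::export]]
Rcpp::List cpp_bn_fw(const arma::cube& X, const arma::vec& mu,
                     const arma::vec& inv_sd, const arma::vec& gamma,
                     const arma::vec& beta) {
  cube xhat(X.n_rows, X.n_cols, X.n_slices);
  cube Y(X.n_rows, X.n_cols, X.n_slices);
  const uword n = X.n_rows, C = X.n_cols;
  for (uword s = 0; s < X.n_slices; ++s) {
    for (uword c = 0; c < C; ++c) {
      const double m = mu(c), isd = inv_sd(c), g = gamma(c), bt = beta(c);
      const double* xp = X.slice_colptr(s, c);
      double* hp = xhat.slice_colptr(s, c);
      double* yp = Y.slice_colptr(s, c);
      for (uword t = 0; t < n; ++t) {
        const double h = (xp[t] - m) * isd;
        hp[t] = h;
        yp[t] = g * h + bt;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("y") = Y);
}

// [[Rcpp::export]]
arma::cube cpp_relu_fw(const arma::cube& X) {
  cube Y = X;
  Y.transform([](double v) { return v > 0 ? v : 0.0; });
  return Y;
}

// backward through ReLU given its output (y > 0 <=> x > 0)
// [[Rcpp::export]]
arma::cube cpp_relu_bw(const arma::cube& Y, const arma::cube& dY) {
  cube dX(Y.n_rows, Y.n_cols, Y.n_slices);
  const uword n = Y.n_elem;
  const double* yp = Y.memptr();
  const double* dp = dY.memptr();
  double* op = dX.memptr();
  for (uword i = 0; i < n; ++i) op[i] = yp[i] > 0 ? dp[i] : 0.0;
  return dX;
}

// inverted dropout drawing from R's RNG stream (honors set.seed)
// [[Rcpp::export]]
Rcpp::List cpp_dropout_fw(const arma::cube& X, double rate) {
  Rcpp::RNGScope scope;
  const double keep = 1.0 - rate;
  cube mask(X.n_rows, X.n_cols, X.n_slices);
  cube Y(X.n_rows, X.n_cols, X.n_slices);
  const uword n = X.n_elem;
  const double* xp = X.memptr();
  double* mp = mask.memptr();
  double* yp = Y.memptr();
  for (uword i = 0; i < n; ++i) {
    const double m = (unif_rand() >= rate) ? 1.0 / keep : 0.0;
    mp[i] = m;
    yp[i] = xp[i] * m;
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("mask") = mask);
}

// [[Rcpp::export]]
arma::cube cpp_mul(const arma::cube& A, const arma::cube& B) {
  return A % B;
}

// Fused batch-norm -> ReLU -> inverted-dropout pass used inside TCN
// residual blocks. cmask carries the combined ReLU gate and dropout
// scale, so the backward pass is dbnout = dY % cmask. The dxhat channel
// moments needed for the batch-norm input gradient follow from dgamma
// and dbeta analytically (m1 = gamma*dbeta/n, m2 = gamma*dgamma/n).
// [[Rcpp::export]]
Rcpp::List cpp_bnad_fw(const arma::cube& X, const arma::vec& gamma,
                       const arma::vec& beta, const arma::vec& mu,
                       const arma::vec& inv_sd, double rate, bool training) {
  Rcpp::RNGScope scope;
  const uword Tn = X.n_rows, C = X.n_cols, B = X.n_slices;
  cube xhat(Tn, C, B), Y(Tn, C, B), cmask(Tn, C, B);
  const double keep = 1.0 - rate;
  const bool drop = training && rate > 0;
  for (uword s = 0; s < B; ++s) {
    for (uword c = 0; c < C; ++c) {
      const double m = mu(c), isd = inv_sd(c), g = gamma(c), bt = beta(c);
      const double* xp = X.slice_colptr(s, c);
      double* hp = xhat.slice_colptr(s, c);
      double* yp = Y.slice_colptr(s, c);
      double* mp = cmask.slice_colptr(s, c);
      for (uword t = 0; t < Tn; ++t) {
        const double h = (xp[t] - m) * isd;
        hp[t] = h;
        const double z = g * h + bt;
        double gate = z > 0 ? 1.0 : 0.0;
        if (drop && gate > 0) gate = (unif_rand() >= rate) ? 1.0 / keep : 0.0;
        mp[t] = gate;
        yp[t] = z * gate;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("cmask") = cmask);
}

// [[Rcpp::export]]
Rcpp::List cpp_bnad_bw(const arma::cube& dY, const arma::cube& xhat,
                       const arma::cube& cmask, const arma::vec& gamma,
                       const arma::vec& inv_sd, bool batch_stats) {
  const uword Tn = dY.n_rows, C = dY.n_cols, B = dY.n_slices;
  const double n = static_cast<double>(Tn) * B;
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  for (uword s = 0; s < B; ++s) {
    for (uword c = 0; c < C; ++c) {
      const double* dp = dY.slice_colptr(s, c);
      const double* hp = xhat.slice_colptr(s, c);
      const double* mp = cmask.slice_colptr(s, c);
      double sg = 0, sb = 0;
      for (uword t = 0; t < Tn; ++t) {
        const double d = dp[t] * mp[t];
        sb += d;
        sg += d * hp[t];
      }
      dgamma(c) += sg;
      dbeta(c) += sb;
    }
  }
  cube dX(Tn, C, B);
  for (uword s = 0; s < B; ++s) {
    for (uword c = 0; c < C; ++c) {
      const double g = gamma(c), isd = inv_sd(c);
      const double m1 = batch_stats ? g * dbeta(c) / n : 0.0;
      const double m2 = batch_stats ? g * dgamma(c) / n : 0.0;
      const double* dp = dY.slice_colptr(s, c);
      const double* hp = xhat.slice_colptr(s, c);
      const double* mp = cmask.slice_colptr(s, c);
      double* op = dX.slice_colptr(s, c);
      for (uword t = 0; t < Tn; ++t)
        op[t] = isd * (dp[t] * mp[t] * g - m1 - hp[t] * m2);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
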