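// Mini-batch Adam training of Poisson-output encoders.
//
// Two families share this file: layered feedforward maps (a GLM is the
// zero-hidden-layer case) and stacked Elman recurrences trained by full
// backpropagation through time over fixed-length subsequences.  The loss is
// the normalized Poisson negative log-likelihood
//   L = (1/(N*B)) * sum_nm ( yhat_nm - y_nm * log(yhat_nm) )
// with an exponential output nonlinearity whose pre-activation is clamped to
// [-CLAMP, CLAMP]; clamped units get zero gradient.
//
// All randomness (batch order) is drawn from R's RNG so results are
// reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double CLAMP = 20.0;

// Fisher-Yates shuffle driven by R's RNG.
static void shuffle_uvec(arma::uvec &v) {
  const arma::uword n = v.n_elem;
  for (arma::uword i = n; i > 1; --i) {
    arma::uword j = (arma::uword)std::floor(unif_rand() * (double)i);
    if (j >= i) j = i - 1;
    std::swap(v[i - 1], v[j]);
  }
}

static arma::mat activate(const arma::mat &z, const int act) {
  if (act == 0) return arma::clamp(z, 0.0, arma::datum::inf); // relu
  return arma::tanh(z);                                       // tanh
}

static arma::mat activate_grad(const arma::mat &h, const int act) {
  if (act == 0) return arma::conv_to<arma::mat>::from(h > 0.0);
  return 1.0 - arma::square(h); // tanh' in terms of the output
}

struct AdamState {
  std::vector<arma::mat> mW, vW;
  std::vector<arma::rowvec> mb, vb;
  double b1t = 1.0, b2t = 1.0;
};

static void adam_step(arma::mat &W, arma::mat &m, arma::mat &v,
                      const arma::mat &g, double lr, double b1, double b2,
                      double eps, double b1t, double b2t) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * arma::square(g);
  const arma::mat mhat = m / (1.0 - b1t);
  const arma::mat vhat = v / (1.0 - b2t);
  W -= lr * mhat / (arma::sqrt(vhat) + eps);
}

static void adam_step_row(arma::rowvec &b, arma::rowvec &m, arma::rowvec &v,
                          const arma::rowvec &g, double lr, double b1,
                          double b2, double eps, double b1t, double b2t) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * arma::square(g);
  const arma::rowvec mhat = m / (1.0 - b1t);
  const arma::rowvec vhat = v / (1.0 - b2t);
  b -= lr * mhat / (arma::sqrt(vhat) + eps);
}

// Weight-decay gradient (biases exempt).  reg: 0 none/early, 1 L1, 2 L2
// (squared-norm convention: penalty lambda * sum(theta^2), gradient
// 2*lambda*theta).
static arma::mat decay_grad(const arma::mat &W, int reg, double lambda) {
  if (reg == 1) return lambda * arma::sign(W);
  if (reg == 2) return 2.0 * lambda * W;
  return arma::zeros<arma::mat>(W.n_rows, W.n_cols);
}

// ---------------------------------------------------------------------------
// Feedforward / GLM
// ---------------------------------------------------------------------------

// Forward pass; fills hs (hidden activations) and returns the clamped
// log-rate matrix A along with the clamp mask.
static arma::mat mlp_forward(const arma::mat &X,
                             const std::vector<arma::mat> &W,
                             const std::vector<arma::rowvec> &b, int act,
                             std::vector<arma::mat> &hs, arma::mat &mask) {
  const size_t L = W.size();
  hs.clear();
  arma::mat a = X;
  for (size_t l = 0; l + 1 < L; ++l) {
    a = activate(a * W[l] + arma::repmat(b[l], a.n_rows, 1), act);
    hs.push_back(a);
  }
  arma::mat z = a * W[L - 1] + arma::repmat(b[L - 1], a.n_rows, 1);
  mask = arma::conv_to<arma::mat>::from(arma::abs(z) <= CLAMP);
  return arma::clamp(z, -CLAMP, CLAMP);
}

static double poisson_loss_rows(const arma::mat &X, const arma::mat &Y,
                                const std::vector<arma::mat> &W,
                                const std::vector<arma::rowvec> &b, int act,
                                const arma::uvec &rows) {
  if (rows.n_elem == 0) return NA_REAL;
  std::vector<arma::mat> hs;
  arma::mat mask;
  const arma::mat Xs = X.rows(rows);
  const arma::mat Ys = Y.rows(rows);
  const arma::mat A = mlp_forward(Xs, W, b, act, hs, mask);
  return arma::accu(arma::exp(A) - Ys % A) / (double)(Ys.n_rows * Ys.n_cols);
}

// [[Rcpp::export]]
arma::mat cpp_predict_mlp(const arma::mat &X, const List &W_, const List &b_,
                          const int act) {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
  for (R_xlen_t i = 0; i < W_.size(); ++i) {
    W.push_back(as<arma::mat>(W_[i]));
    b.push_back(as<arma::rowvec>(b_[i]));
  }
  std::vector<arma::mat> hs;
  arma::mat mask;
  const arma::mat A = mlp_forward(X, W, b, act, hs, mask);
  return arma::exp(A);
}

// [[Rcpp::export]]
List cpp_fit_mlp(const arma::mat &X, const arma::mat &Y, const List &W0,
                 const List &b0, const arma::uvec &train_idx,
                 const arma::uvec &val_idx, const int act,
                 const int batch_size, const int max_epochs, const int reg,
                 const double lambda, const double lr, const double beta1,
                 const double beta2, const double eps) {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
  for (R_xlen_t i = 0; i < W0.size(); ++i) {
    W.push_back(as<arma::mat>(W0[i]));
    b.push_back(as<arma::rowvec>(b0[i]));
  }
  const size_t L = W.size();
  const double Nn = (double)Y.n_cols;

  AdamState st;
  for (size_t l = 0; l < L; ++l) {
    st.mW.push_back(arma::zeros<arma::mat>(W[l].n_rows, W[l].n_cols));
    st.vW.push_back(arma::zeros<arma::mat>(W[l].n_rows, W[l].n_cols));
    st.mb.push_back(arma::zeros<arma::rowvec>(b[l].n_elem));
    st.vb.push_back(arma::zeros<arma::rowvec>(b[l].n_elem));
  }

  std::vector<double> train_hist, val_hist;
  std::vector<arma::mat> snapW = W;
  std::vector<arma::rowvec> snapb = b;
  std::string stop_reason = "max_epochs";
  int stop_epoch = max_epochs;
  arma::uvec order = train_idx;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    shuffle_uvec(order);
    const arma::uword M = order.n_elem;
    for (arma::uword s = 0; s < M; s += (arma::uword)batch_size) {
      const arma::uword e = std::min(M, s + (arma::uword)batch_size);
      const arma::uvec rows = order.subvec(s, e - 1);
      const arma::mat Xb = X.rows(rows);
      const arma::mat Yb = Y.rows(rows);
      const double Bm = (double)Xb.n_rows;

      std::vector<arma::mat> hs;
      arma::mat mask;
      const arma::mat A = mlp_forward(Xb, W, b, act, hs, mask);
      // dL/dA, zero where the clamp is active
      arma::mat delta = (arma::exp(A) - Yb) % mask / (Nn * Bm);

      st.b1t *= beta1;
      st.b2t *= beta2;

      // backprop from the output layer down
      for (int l = (int)L - 1; l >= 0; --l) {
        const arma::mat &input = (l == 0) ? Xb : hs[l - 1];
        arma::mat gW = input.t() * delta + decay_grad(W[l], reg, lambda);
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = (delta * W[l].t()) % activate_grad(hs[l - 1], act);
        }
        adam_step(W[l], st.mW[l], st.vW[l], gW, lr, beta1, beta2, eps, st.b1t,
                  st.b2t);
        adam_step_row(b[l], st.mb[l], st.vb[l], gb, lr, beta1, beta2, eps,
                      st.b1t, st.b2t);
      }
    }

    train_hist.push_back(poisson_loss_rows(X, Y, W, b, act, train_idx));
    val_hist.push_back(poisson_loss_rows(X, Y, W, b, act, val_idx));

    if (!std::isfinite(train_hist.back()))
      stop("training loss became non-finite at epoch %d", epoch);

    if (reg == 3 && epoch >= 2 &&
        val_hist[epoch - 1] > val_hist[epoch - 2]) { // strict increase
      // revert to the parameters from the preceding epoch
      W = snapW;
      b = snapb;
      stop_reason = "early_stop";
      stop_epoch = epoch - 1;
      break;
    }
    snapW = W;
    snapb = b;
    if (epoch == max_epochs) stop_epoch = max_epochs;
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = b[l];
  }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["train_loss"] = train_hist, _["val_loss"] = val_hist,
                      _["stop_epoch"] = stop_epoch,
                      _["stop_reason"] = stop_reason);
}

// ---------------------------------------------------------------------------
// Stacked Elman recurrence
// ---------------------------------------------------------------------------

struct RnnParams {
  std::vector<arma::mat> Wx, Wh;
  std::vector<arma::rowvec> bh;
  arma::mat Wo;
  arma::rowvec bo;
};

// Forward a batch of B equal-length sequences; H[l] holds B x n_l x (T+1)
// hidden states with the zero initial state in slice 0.
static void rnn_forward_batch(const arma::mat &X, const arma::uvec &starts,
                              const int T, const RnnParams &p,
                              std::vector<arma::cube> &H,
                              std::vector<arma::mat> &A,
                              std::vector<arma::mat> &Mask) {
  const size_t L = p.Wx.size();
  const arma::uword B = starts.n_elem;
  H.assign(L, arma::cube());
  for (size_t l = 0; l < L; ++l)
    H[l] = arma::zeros<arma::cube>(B, p.Wx[l].n_cols, T + 1);
  A.assign(T, arma::mat());
  Mask.assign(T, arma::mat());

  for (int t = 0; t < T; ++t) {
    arma::mat in(B, X.n_cols);
    for (arma::uword i = 0; i < B; ++i) in.row(i) = X.row(starts[i] + t);
    for (size_t l = 0; l < L; ++l) {
      const arma::mat hin = (l == 0) ? in : H[l - 1].slice(t + 1);
      arma::mat z = hin * p.Wx[l] + H[l].slice(t) * p.Wh[l] +
                    arma::repmat(p.bh[l], B, 1);
      H[l].slice(t + 1) = arma::tanh(z);
    }
    arma::mat z = H[L - 1].slice(t + 1) * p.Wo + arma::repmat(p.bo, B, 1);
    Mask[t] = arma::conv_to<arma::mat>::from(arma::abs(z) <= CLAMP);
    A[t] = arma::clamp(z, -CLAMP, CLAMP);
  }
}

static double rnn_loss_batch(const arma::mat &X, const arma::mat &Y,
                             const arma::uvec &starts, const int T,
                             const RnnParams &p) {
  if (starts.n_elem == 0) return NA_REAL;
  std::vector<arma::cube> H;
  std::vector<arma::mat> A, Mask;
  rnn_forward_batch(X, starts, T, p, H, A, Mask);
  double acc = 0.0;
  const arma::uword B = starts.n_elem;
  for (int t = 0; t < T; ++t) {
    arma::mat Yt(B, Y.n_cols);
    for (arma::uword i = 0; i < B; ++i) Yt.row(i) = Y.row(starts[i] + t);
    acc += arma::accu(arma::exp(A[t]) - Yt % A[t]);
  }
  return acc / (double)(B * T * Y.n_cols);
}

// [[Rcpp::export]]
arma::mat cpp_predict_rnn(const arma::mat &X, const List &Wx_, const List &Wh_,
                          const List &bh_, const arma::mat &Wo,
                          const arma::rowvec &bo) {
  RnnParams p;
  for (R_xlen_t i = 0; i < Wx_.size(); ++i) {
    p.Wx.push_back(as<arma::mat>(Wx_[i]));
    p.Wh.push_back(as<arma::mat>(Wh_[i]));
    p.bh.push_back(as<arma::rowvec>(bh_[i]));
  }
  p.Wo = Wo;
  p.bo = bo;
  arma::uvec starts(1);
  starts[0] = 0;
  std::vector<arma::cube> H;
  std::vector<arma::mat> A, Mask;
  rnn_forward_batch(X, starts, (int)X.n_rows, p, H, A, Mask);
  arma::mat out(X.n_rows, Wo.n_cols);
  for (arma::uword t = 0; t < X.n_rows; ++t) out.row(t) = arma::exp(A[t]);
  return out;
}

// [[Rcpp::export]]
List cpp_fit_rnn(const arma::mat &X, const arma::mat &Y, const List &Wx0,
                 const List &Wh0, const List &bh0, const arma::mat &Wo0,
                 const arma::rowvec &bo0, const arma::uvec &starts_train,
                 const arma::uvec &starts_val, const int T,
                 const int batch_seqs, const int max_epochs, const int reg,
                 const double lambda, const double lr, const double beta1,
                 const double beta2, const double eps) {
  RnnParams p;
  for (R_xlen_t i = 0; i < Wx0.size(); ++i) {
    p.Wx.push_back(as<arma::mat>(Wx0[i]));
    p.Wh.push_back(as<arma::mat>(Wh0[i]));
    p.bh.push_back(as<arma::rowvec>(bh0[i]));
  }
  p.Wo = Wo0;
  p.bo = bo0;
  const size_t L = p.Wx.size();
  const double Nn = (double)Y.n_cols;

  // Adam state for every parameter block
  std::vector<arma::mat> mWx, vWx, mWh, vWh;
  std::vector<arma::rowvec> mbh, vbh;
  for (size_t l = 0; l < L; ++l) {
    mWx.push_back(arma::zeros<arma::mat>(p.Wx[l].n_rows, p.Wx[l].n_cols));
    vWx.push_back(arma::zeros<arma::mat>(p.Wx[l].n_rows, p.Wx[l].n_cols));
    mWh.push_back(arma::zeros<arma::mat>(p.Wh[l].n_rows, p.Wh[l].n_cols));
    vWh.push_back(arma::zeros<arma::mat>(p.Wh[l].n_rows, p.Wh[l].n_cols));
    mbh.push_back(arma::zeros<arma::rowvec>(p.bh[l].n_elem));
    vbh.push_back(arma::zeros<arma::rowvec>(p.bh[l].n_elem));
  }
  arma::mat mWo = arma::zeros<arma::mat>(p.Wo.n_rows, p.Wo.n_cols), vWo = mWo;
  arma::rowvec mbo = arma::zeros<arma::rowvec>(p.bo.n_elem), vbo = mbo;
  double b1t = 1.0, b2t = 1.0;

  std::vector<double> train_hist, val_hist;
  RnnParams snap = p;
  std::string stop_reason = "max_epochs";
  int stop_epoch = max_epochs;
  arma::uvec order = starts_train;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    shuffle_uvec(order);
    const arma::uword S = order.n_elem;
    for (arma::uword s0 = 0; s0 < S; s0 += (arma::uword)batch_seqs) {
      const arma::uword e0 = std::min(S, s0 + (arma::uword)batch_seqs);
      const arma::uvec starts = order.subvec(s0, e0 - 1);
      const arma::uword B = starts.n_elem;

      std::vector<arma::cube> H;
      std::vector<arma::mat> A, Mask;
      rnn_forward_batch(X, starts, T, p, H, A, Mask);

      // gradient accumulators
      std::vector<arma::mat> gWx(L), gWh(L);
      std::vector<arma::rowvec> gbh(L);
      for (size_t l = 0; l < L; ++l) {
        gWx[l] = arma::zeros<arma::mat>(p.Wx[l].n_rows, p.Wx[l].n_cols);
        gWh[l] = arma::zeros<arma::mat>(p.Wh[l].n_rows, p.Wh[l].n_cols);
        gbh[l] = arma::zeros<arma::rowvec>(p.bh[l].n_elem);
      }
      arma::mat gWo = arma::zeros<arma::mat>(p.Wo.n_rows, p.Wo.n_cols);
      arma::rowvec gbo = arma::zeros<arma::rowvec>(p.bo.n_elem);
      // carried dL/dh for each layer (to time t-1)
      std::vector<arma::mat> dh_next(L);
      for (size_t l = 0; l < L; ++l)
        dh_next[l] = arma::zeros<arma::mat>(B, p.Wx[l].n_cols);

      const double scale = Nn * (double)B * (double)T;
      for (int t = T - 1; t >= 0; --t) {
        arma::mat Yt(B, Y.n_cols);
        arma::mat in(B, X.n_cols);
        for (arma::uword i = 0; i < B; ++i) {
          Yt.row(i) = Y.row(starts[i] + t);
          in.row(i) = X.row(starts[i] + t);
        }
        const arma::mat da = (arma::exp(A[t]) - Yt) % Mask[t] / scale;
        gWo += H[L - 1].slice(t + 1).t() * da;
        gbo += arma::sum(da, 0);
        arma::mat dh_same = da * p.Wo.t(); // into top layer at time t
        for (int l = (int)L - 1; l >= 0; --l) {
          const arma::mat h = H[l].slice(t + 1);
          const arma::mat dz = (dh_same + dh_next[l]) % (1.0 - arma::square(h));
          const arma::mat hin = (l == 0) ? in : H[l - 1].slice(t + 1);
          gWx[l] += hin.t() * dz;
          gWh[l] += H[l].slice(t).t() * dz;
          gbh[l] += arma::sum(dz, 0);
          dh_next[l] = dz * p.Wh[l].t();
          dh_same = (l > 0) ? arma::mat(dz * p.Wx[l].t())
                            : arma::zeros<arma::mat>(B, 1);
        }
      }

      b1t *= beta1;
      b2t *= beta2;
      for (size_t l = 0; l < L; ++l) {
        adam_step(p.Wx[l], mWx[l], vWx[l],
                  gWx[l] + decay_grad(p.Wx[l], reg, lambda), lr, beta1, beta2,
                  eps, b1t, b2t);
        adam_step(p.Wh[l], mWh[l], vWh[l],
                  gWh[l] + decay_grad(p.Wh[l], reg, lambda), lr, beta1, beta2,
                  eps, b1t, b2t);
        adam_step_row(p.bh[l], mbh[l], vbh[l], gbh[l], lr, beta1, beta2, eps,
                      b1t, b2t);
      }
      adam_step(p.Wo, mWo, vWo, gWo + decay_grad(p.Wo, reg, lambda), lr, beta1,
                beta2, eps, b1t, b2t);
      adam_step_row(p.bo, mbo, vbo, gbo, lr, beta1, beta2, eps, b1t, b2t);
    }

    train_hist.push_back(rnn_loss_batch(X, Y, starts_train, T, p));
    val_hist.push_back(rnn_loss_batch(X, Y, starts_val, T, p));
    if (!std::isfinite(train_hist.back()))
      stop("training loss became non-finite at epoch %d", epoch);

    if (reg == 3 && epoch >= 2 &&
        val_hist[epoch - 1] > val_hist[epoch - 2]) {
      p = snap;
      stop_reason = "early_stop";
      stop_epoch = epoch - 1;
      break;
    }
    snap = p;
    if (epoch == max_epochs) stop_epoch = max_epochs;
  }

  List Wx(L), Wh(L), bh(L);
  for (size_t l = 0; l < L; ++l) {
    Wx[l] = p.Wx[l];
    Wh[l] = p.Wh[l];
    bh[l] = p.bh[l];
  }
  return List::create(_["Wx"] = Wx, _["Wh"] = Wh, _["bh"] = bh,
                      _["Wo"] = p.Wo, _["bo"] = p.bo,
                      _["train_loss"] = train_hist, _["val_loss"] = val_hist,
                      _["stop_epoch"] = stop_epoch,
                      _["stop_reason"] = stop_reason);
}
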