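// 1-D convolutional network for DNA sequence classification.
// Layout convention: activations are (channels x positions*batch), column-major,
// so the block of columns [b*L, (b+1)*L) belongs to example b and a
// reshape to (channels*L, batch) flattens per example without copying order.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS_P = 1e-12;

static inline void relu_inplace(mat& A) {
  double* p = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
}

// zero the entries of G where the pre-activation Z was non-positive
static inline void relu_mask(mat& G, const mat& Z) {
  double* g = G.memptr();
  const double* z = Z.memptr();
  const uword n = G.n_elem;
  for (uword i = 0; i < n; ++i)
    if (z[i] <= 0) g[i] = 0;
}

// im2col restricted to within-example columns: (C x Lin*B) -> (C*w x Lout*B)
static mat im2col(const mat& A, int Lin, int B, int w) {
  const int C = A.n_rows, Lout = Lin - w + 1;
  mat M(C * w, (uword)Lout * B);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < w; ++k)
      M.submat(k * C, (uword)b * Lout, (k + 1) * C - 1, (uword)(b + 1) * Lout - 1) =
        A.cols((uword)b * Lin + k, (uword)b * Lin + k + Lout - 1);
  return M;
}

// adjoint of im2col (scatter-add)
static mat col2im(const mat& G, int Lin, int B, int w, int C) {
  const int Lout = Lin - w + 1;
  mat A(C, (uword)Lin * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < w; ++k)
      A.cols((uword)b * Lin + k, (uword)b * Lin + k + Lout - 1) +=
        G.submat(k * C, (uword)b * Lout, (k + 1) * C - 1, (uword)(b + 1) * Lout - 1);
  return A;
}

// non-overlapping pooling of width p within each example; remainder dropped.
// mode 0 = max (argmax recorded for backprop), mode 1 = average.
static void pool_fwd(const mat& A, int Lout, int B, int p, int mode,
                     mat& P, umat& idx) {
  const int nk = A.n_rows, Lp = Lout / p;
  P.set_size(nk, (uword)Lp * B);
  if (mode == 0) idx.set_size(nk, (uword)Lp * B);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < Lp; ++j) {
      const uword outc = (uword)b * Lp + j;
      const uword c0 = (uword)b * Lout + (uword)j * p;
      if (mode == 0) {
        for (int r = 0; r < nk; ++r) {
          double best = A(r, c0);
          uword bi = c0;
          for (int q = 1; q < p; ++q)
            if (A(r, c0 + q) > best) { best = A(r, c0 + q); bi = c0 + q; }
          P(r, outc) = best;
          idx(r, outc) = bi;
        }
      } else {
        for (int r = 0; r < nk; ++r) {
          double s = 0;
          for (int q = 0; q < p; ++q) s += A(r, c0 + q);
          P(r, outc) = s / p;
        }
      }
    }
}

// one-hot encode integer codes 0..3 (4 = unknown -> all-zero column)
static mat one_hot(const Rcpp::IntegerMatrix& X, const std::vector<int>& rows) {
  const int L = X.ncol(), B = (int)rows.size();
  mat A(4, (uword)L * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < L; ++j) {
      int code = X(rows[b], j);
      if (code >= 0 && code <= 3) A(code, (uword)b * L + j) = 1.0;
    }
  return A;
}

struct LayerCache {
  mat M;    // im2col of layer input
  mat Z;    // post-ReLU activation (ReLU applied in place; the backward
            // mask A > 0 coincides with Z_pre > 0 almost everywhere)
  umat idx; // pool argmax (columns of Z)
  int Lout, Lp;
};

struct Net {
  std::vector<mat> Wc;
  std::vector<vec> bc;
  std::vector<int> width, pool;
  mat W1; vec b1;
  mat W2; double b2;
};

static Net net_from_list(const Rcpp::List& weights,
                         const Rcpp::IntegerVector& widths,
                         const Rcpp::IntegerVector& pools) {
  Net net;
  Rcpp::List cw = weights["conv_W"], cb = weights["conv_b"];
  for (int l = 0; l < cw.size(); ++l) {
    net.Wc.push_back(Rcpp::as<mat>(cw[l]));
    net.bc.push_back(Rcpp::as<vec>(cb[l]));
    net.width.push_back(widths[l]);
    net.pool.push_back(pools[l]);
  }
  net.W1 = Rcpp::as<mat>(weights["W1"]);
  net.b1 = Rcpp::as<vec>(weights["b1"]);
  net.W2 = Rcpp::as<mat>(weights["W2"]);
  net.b2 = Rcpp::as<double>(weights["b2"]);
  return net;
}

static Rcpp::List net_to_list(const Net& net) {
  Rcpp::List cw(net.Wc.size()), cb(net.bc.size());
  for (size_t l = 0; l < net.Wc.size(); ++l) { cw[l] = net.Wc[l]; cb[l] = net.bc[l]; }
  return Rcpp::List::create(
    Rcpp::Named("conv_W") = cw, Rcpp::Named("conv_b") = cb,
    Rcpp::Named("W1") = net.W1, Rcpp::Named("b1") = net.b1,
    Rcpp::Named("W2") = net.W2, Rcpp::Named("b2") = net.b2);
}

// forward pass; caches filled only when training
static rowvec forward(const Net& net, const mat& A0, int L, int B,
                      std::vector<LayerCache>* caches, mat& H0, mat& Z1, mat& A1d,
                      const mat* drop_mask) {
  mat P = A0;
  int Lin = L;
  for (size_t l = 0; l < net.Wc.size(); ++l) {
    LayerCache cc;
    cc.Lout = Lin - net.width[l] + 1;
    cc.M = im2col(P, Lin, B, net.width[l]);
    cc.Z = net.Wc[l] * cc.M;
    cc.Z.each_col() += net.bc[l];
    relu_inplace(cc.Z);
    // negative pool width encodes average pooling of width |p|
    const int p = std::abs(net.pool[l]);
    pool_fwd(cc.Z, cc.Lout, B, p, net.pool[l] < 0 ? 1 : 0, P, cc.idx);
    cc.Lp = cc.Lout / p;
    Lin = cc.Lp;
    if (caches) caches->push_back(std::move(cc));
  }
  H0 = reshape(P, P.n_rows * Lin, B); // per-example flatten
  Z1 = net.W1 * H0;
  Z1.each_col() += net.b1;
  A1d = Z1;
  relu_inplace(A1d);
  if (drop_mask) A1d %= *drop_mask; // inverted dropout, mask pre-scaled
  rowvec z2 = net.W2 * A1d + net.b2;
  return 1.0 / (1.0 + exp(-z2));
}

static double bce(const rowvec& p, const rowvec& y) {
  rowvec pc = clamp(p, EPS_P, 1.0 - EPS_P);
  return -mean(y % log(pc) + (1.0 - y) % log(1.0 - pc));
}

// backward pass; returns gradients in a Net of identical shapes
static Net backward(const Net& net, const std::vector<LayerCache>& caches,
                    const mat& A0, int L, int B, const mat& H0, const mat& Z1,
                    const mat& A1d, const mat* drop_mask,
                    const rowvec& p, const rowvec& y) {
  Net g = net; // shape template
  rowvec dz2 = (p - y) / (double)B;
  g.W2 = dz2 * A1d.t();
  g.b2 = accu(dz2);
  mat dA1 = net.W2.t() * dz2;
  if (drop_mask) dA1 %= *drop_mask;
  mat dZ1 = dA1;
  relu_mask(dZ1, Z1);
  g.W1 = dZ1 * H0.t();
  g.b1 = sum(dZ1, 1);
  mat dH0 = net.W1.t() * dZ1;
  const int nL = (int)net.Wc.size();
  mat dP = reshape(dH0, net.Wc[nL - 1].n_rows, (uword)caches[nL - 1].Lp * B);
  for (int l = nL - 1; l >= 0; --l) {
    const LayerCache& cc = caches[l];
    mat dA(cc.Z.n_rows, cc.Z.n_cols, fill::zeros); // unpool
    const int p = std::abs(net.pool[l]);
    if (net.pool[l] < 0) { // average pooling: spread gradient uniformly
      for (int b = 0; b < B; ++b)
        for (int j = 0; j < cc.Lp; ++j) {
          const uword outc = (uword)b * cc.Lp + j;
          const uword c0 = (uword)b * cc.Lout + (uword)j * p;
          for (uword r = 0; r < dP.n_rows; ++r) {
            const double g1 = dP(r, outc) / p;
            for (int q = 0; q < p; ++q) dA(r, c0 + q) += g1;
          }
        }
    } else {
      for (uword c = 0; c < dP.n_cols; ++c)
        for (uword r = 0; r < dP.n_rows; ++r)
          dA(r, cc.idx(r, c)) += dP(r, c);
    }
    mat dZ = std::move(dA);
    relu_mask(dZ, cc.Z);
    g.Wc[l] = dZ * cc.M.t();
    g.bc[l] = sum(dZ, 1);
    mat dM = net.Wc[l].t() * dZ;
    const int C = (l == 0) ? 4 : (int)net.Wc[l - 1].n_rows;
    const int Lin = (l == 0) ? L : caches[l - 1].Lp;
    mat dAprev = col2im(dM, Lin, B, net.width[l], C);
    if (l > 0) dP = dAprev;
  }
  return g;
}

// [[Rcpp::export]]
Rcpp::List cnn_init_weights(Rcpp::IntegerVector n_kernels,
                            Rcpp::IntegerVector widths,
                            Rcpp::IntegerVector pools,
                            int dense_units, int input_len, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  Net net;
  int C = 4, Lin = input_len;
  for (int l = 0; l < n_kernels.size(); ++l) {
    const int nk = n_kernels[l], w = widths[l], p = std::abs(pools[l]);
    const int Lout = Lin - w + 1;
    if (Lout < 1) Rcpp::stop("conv layer %d: input length %d shorter than kernel width %d",
                             l + 1, Lin, w);
    if (Lout / p < 1) Rcpp::stop("conv layer %d: pooled length is zero", l + 1);
    mat W(nk, C * w);
    const double sd = std::sqrt(2.0 / (C * w)); // He init
    for (uword i = 0; i < W.n_elem; ++i) W(i) = sd * norm(rng);
    net.Wc.push_back(W);
    net.bc.push_back(vec(nk, fill::zeros));
    net.width.push_back(w);
    net.pool.push_back(p);
    C = nk;
    Lin = Lout / p;
  }
  const int D = C * Lin;
  mat W1(dense_units, D);
  double sd1 = std::sqrt(2.0 / D);
  for (uword i = 0; i < W1.n_elem; ++i) W1(i) = sd1 * norm(rng);
  net.W1 = W1;
  net.b1 = vec(dense_units, fill::zeros);
  mat W2(1, dense_units);
  double sd2 = std::sqrt(2.0 / dense_units);
  for (uword i = 0; i < W2.n_elem; ++i) W2(i) = sd2 * norm(rng);
  net.W2 = W2;
  net.b2 = 0.0;
  return net_to_list(net);
}

// loss (and optionally gradients) at given weights; dropout disabled.
// [[Rcpp::export]]
Rcpp::List cnn_loss_grad(Rcpp::List weights, Rcpp::IntegerMatrix X,
                         Rcpp::NumericVector y, Rcpp::IntegerVector widths,
                         Rcpp::IntegerVector pools, bool compute_grad = true) {
  Net net = net_from_list(weights, widths, pools);
  const int B = X.nrow(), L = X.ncol();
  std::vector<int> rows(B);
  for (int i = 0; i < B; ++i) rows[i] = i;
  mat A0 = one_hot(X, rows);
  std::vector<LayerCache> caches;
  mat H0, Z1, A1d;
  rowvec yv(B);
  for (int i = 0; i < B; ++i) yv(i) = y[i];
  rowvec p = forward(net, A0, L, B, &caches, H0, Z1, A1d, nullptr);
  double loss = bce(p, yv);
  if (!compute_grad)
    return Rcpp::List::create(Rcpp::Named("loss") = loss);
  Net g = backward(net, caches, A0, L, B, H0, Z1, A1d, nullptr, p, yv);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = net_to_list(g));
}

// [[Rcpp::export]]
Rcpp::NumericVector cnn_predict_cpp(Rcpp::List weights, Rcpp::IntegerMatrix X,
                                    Rcpp::IntegerVector widths,
                                    Rcpp::IntegerVector pools,
                                    int batch_size = 256) {
  Net net = net_from_list(weights, widths, pools);
  const int n = X.nrow(), L = X.ncol();
  Rcpp::NumericVector out(n);
  mat H0, Z1, A1d;
  for (int start = 0; start < n; start += batch_size) {
    const int B = std::min(batch_size, n - start);
    std::vector<int> rows(B);
    for (int i = 0; i < B; ++i) rows[i] = start + i;
    mat A0 = one_hot(X, rows);
    rowvec p = forward(net, A0, L, B, nullptr, H0, Z1, A1d, nullptr);
    for (int i = 0; i < B; ++i) out[start + i] = p(i);
  }
  return out;
}

struct AdamState {
  std::vector<mat> mWc, vWc;
  std::vector<vec> mbc, vbc;
  mat mW1, vW1, mW2, vW2;
  vec mb1, vb1;
  double mb2 = 0, vb2 = 0;
  long t = 0;
};

static void adam_update_mat(mat& W, const mat& g, mat& m, mat& v,
                            double lr, double b1c, double b2c) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * square(g);
  W -= lr * (m / b1c) / (sqrt(v / b2c) + 1e-8);
}
static void adam_update_vec(vec& W, const vec& g, vec& m, vec& v,
                            double lr, double b1c, double b2c) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * square(g);
  W -= lr * (m / b1c) / (sqrt(v / b2c) + 1e-8);
}

static double eval_loss(const Net& net, const Rcpp::IntegerMatrix& X,
                        const rowvec& y, int batch_size) {
  const int n = X.nrow(), L = X.ncol();
  mat H0, Z1, A1d;
  double tot = 0;
  for (int start = 0; start < n; start += batch_size) {
    const int B = std::min(batch_size, n - start);
    std::vector<int> rows(B);
    for (int i = 0; i < B; ++i) rows[i] = start + i;
    mat A0 = one_hot(X, rows);
    rowvec p = forward(net, A0, L, B, nullptr, H0, Z1, A1d, nullptr);
    tot += bce(p, y.subvec(start, start + B - 1)) * B;
  }
  return tot / n;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::IntegerMatrix Xtr, Rcpp::NumericVector ytr,
                         Rcpp::IntegerMatrix Xval, Rcpp::NumericVector yval,
                         Rcpp::IntegerVector n_kernels, Rcpp::IntegerVector widths,
                         Rcpp::IntegerVector pools, int dense_units,
                         double dropout, double lr, int batch_size,
                         int max_epochs, int patience, int seed,
                         int min_epochs = 1, bool verbose = false) {
  const int n = Xtr.nrow(), L = Xtr.ncol();
  Rcpp::List w0 = cnn_init_weights(n_kernels, widths, pools, dense_units, L, seed);
  Net net = net_from_list(w0, widths, pools);
  std::mt19937_64 rng((uint64_t)seed + 0x9e3779b97f4a7c15ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  AdamState st;
  for (size_t l = 0; l < net.Wc.size(); ++l) {
    st.mWc.push_back(mat(size(net.Wc[l]), fill::zeros));
    st.vWc.push_back(mat(size(net.Wc[l]), fill::zeros));
    st.mbc.push_back(vec(size(net.bc[l]), fill::zeros));
    st.vbc.push_back(vec(size(net.bc[l]), fill::zeros));
  }
  st.mW1 = mat(size(net.W1), fill::zeros); st.vW1 = st.mW1;
  st.mb1 = vec(size(net.b1), fill::zeros); st.vb1 = st.mb1;
  st.mW2 = mat(size(net.W2), fill::zeros); st.vW2 = st.mW2;

  rowvec yv(Xval.nrow());
  for (int i = 0; i < Xval.nrow(); ++i) yv(i) = yval[i];

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Net best = net;
  double best_val = datum::inf;
  int bad_epochs = 0;
  std::vector<double> tr_hist, val_hist;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int B = std::min(batch_size, n - start);
      std::vector<int> rows(order.begin() + start, order.begin() + start + B);
      mat A0 = one_hot(Xtr, rows);
      rowvec yb(B);
      for (int i = 0; i < B; ++i) yb(i) = ytr[rows[i]];

      mat* dmask_ptr = nullptr;
      mat dmask;
      if (dropout > 0) {
        dmask.set_size(net.W1.n_rows, B);
        const double keep = 1.0 - dropout;
        for (uword i = 0; i < dmask.n_elem; ++i)
          dmask(i) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
        dmask_ptr = &dmask;
      }

      std::vector<LayerCache> caches;
      mat H0, Z1, A1d;
      rowvec p = forward(net, A0, L, B, &caches, H0, Z1, A1d, dmask_ptr);
      ep_loss += bce(p, yb);
      ++n_batches;
      Net g = backward(net, caches, A0, L, B, H0, Z1, A1d, dmask_ptr, p, yb);

      st.t += 1;
      const double b1c = 1.0 - std::pow(0.9, (double)st.t);
      const double b2c = 1.0 - std::pow(0.999, (double)st.t);
      for (size_t l = 0; l < net.Wc.size(); ++l) {
        adam_update_mat(net.Wc[l], g.Wc[l], st.mWc[l], st.vWc[l], lr, b1c, b2c);
        adam_update_vec(net.bc[l], g.bc[l], st.mbc[l], st.vbc[l], lr, b1c, b2c);
      }
      adam_update_mat(net.W1, g.W1, st.mW1, st.vW1, lr, b1c, b2c);
      adam_update_vec(net.b1, g.b1, st.mb1, st.vb1, lr, b1c, b2c);
      adam_update_mat(net.W2, g.W2, st.mW2, st.vW2, lr, b1c, b2c);
      {
        st.mb2 = 0.9 * st.mb2 + 0.1 * g.b2;
        st.vb2 = 0.999 * st.vb2 + 0.001 * g.b2 * g.b2;
        net.b2 -= lr * (st.mb2 / b1c) / (std::sqrt(st.vb2 / b2c) + 1e-8);
      }
    }
    const double val_loss = eval_loss(net, Xval, yv, std::max(batch_size, 256));
    tr_hist.push_back(ep_loss / n_batches);
    val_hist.push_back(val_loss);
    if (verbose)
      Rcpp::Rcout << "epoch " << epoch + 1 << " train " << ep_loss / n_batches
                  << " val " << val_loss << "\n";
    if (val_loss < best_val - 1e-6) {
      best_val = val_loss;
      best = net;
      bad_epochs = 0;
    } else if (++bad_epochs >= patience && epoch + 1 >= min_epochs) break;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = net_to_list(best),
    Rcpp::Named("best_val_loss") = best_val,
    Rcpp::Named("train_loss") = tr_hist,
    Rcpp::Named("val_loss") = val_hist);
}
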