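// Compact neural-network training core for FOG window classifiers.
//
// Activations are kept as (T*B x F) matrices (time fastest, batch blocks of T
// rows) so 1-D convolutions become im2col + one BLAS matmul. Everything is
// seeded through a private mt19937 stream: training is a pure function of
// (data, config, seed).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Rng {
  std::mt19937 gen;
  explicit Rng(unsigned int seed) : gen(seed) {}
  double unif() {
    // 32 random bits -> [0,1); fixed mapping, implementation-independent
    return gen() * (1.0 / 4294967296.0);
  }
  mat uniform_mat(uword r, uword c, double lo, double hi) {
    mat m(r, c);
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i) m(i, j) = lo + (hi - lo) * unif();
    return m;
  }
  void shuffle(std::vector<uword>& v) {
    for (size_t i = v.size(); i > 1; --i) {
      size_t j = static_cast<size_t>(unif() * i);
      if (j >= i) j = i - 1;
      std::swap(v[i - 1], v[j]);
    }
  }
};

mat glorot(Rng& rng, uword fan_in, uword fan_out, uword r, uword c) {
  double lim = std::sqrt(6.0 / (double)(fan_in + fan_out));
  return rng.uniform_mat(r, c, -lim, lim);
}

// im2col for "same" 1-D convolution, dilation 1.
// X: (T*B x C); out: (T*B x k*C), column c*k + j holds X shifted by (j - pad).
mat im2col(const mat& X, uword T, uword B, uword k, int pad) {
  uword C = X.n_cols;
  mat out(X.n_rows, k * C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < k; ++j) {
      int off = (int)j - pad;  // source index = t + off
      uword col = c * k + j;
      for (uword b = 0; b < B; ++b) {
        uword base = b * T;
        int t0 = std::max(0, -off);          // first valid output t
        int t1 = (int)T - 1 - std::max(0, off);
        if (t1 < t0) continue;
        out.col(col).subvec(base + t0, base + t1) =
            X.col(c).subvec(base + t0 + off, base + t1 + off);
      }
    }
  }
  return out;
}

// Scatter-add transpose of im2col.
void col2im_add(mat& dX, const mat& dCols, uword T, uword B, uword k, int pad) {
  uword C = dX.n_cols;
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < k; ++j) {
      int off = (int)j - pad;
      uword col = c * k + j;
      for (uword b = 0; b < B; ++b) {
        uword base = b * T;
        int t0 = std::max(0, -off);
        int t1 = (int)T - 1 - std::max(0, off);
        if (t1 < t0) continue;
        dX.col(c).subvec(base + t0 + off, base + t1 + off) +=
            dCols.col(col).subvec(base + t0, base + t1);
      }
    }
  }
}

struct PoolCache { umat argmax; };

// Non-overlapping max pool of size `pool` along time.
mat maxpool(const mat& X, uword T, uword B, uword pool, PoolCache& cache) {
  uword T2 = T / pool, F = X.n_cols;
  mat out(T2 * B, F);
  cache.argmax.set_size(T2 * B, F);
  for (uword f = 0; f < F; ++f) {
    for (uword b = 0; b < B; ++b) {
      for (uword t = 0; t < T2; ++t) {
        uword best = b * T + t * pool;
        double bv = X(best, f);
        for (uword p = 1; p < pool; ++p) {
          uword idx = b * T + t * pool + p;
          if (X(idx, f) > bv) { bv = X(idx, f); best = idx; }
        }
        out(b * T2 + t, f) = bv;
        cache.argmax(b * T2 + t, f) = best;
      }
    }
  }
  return out;
}

mat maxpool_backward(const mat& dY, uword T, uword B, const PoolCache& cache) {
  mat dX(T * B, dY.n_cols, fill::zeros);
  for (uword f = 0; f < dY.n_cols; ++f)
    for (uword i = 0; i < dY.n_rows; ++i)
      dX(cache.argmax(i, f), f) += dY(i, f);
  return dX;
}

// Sliding max pool size 3, stride 1, same padding (for inception pool branch).
mat maxpool3_same(const mat& X, uword T, uword B, umat& argmax) {
  mat out(X.n_rows, X.n_cols);
  argmax.set_size(X.n_rows, X.n_cols);
  for (uword f = 0; f < X.n_cols; ++f) {
    for (uword b = 0; b < B; ++b) {
      for (uword t = 0; t < T; ++t) {
        uword lo = b * T + (t == 0 ? 0 : t - 1);
        uword hi = b * T + std::min(T - 1, t + 1);
        uword best = lo;
        for (uword i = lo + 1; i <= hi; ++i)
          if (X(i, f) > X(best, f)) best = i;
        out(b * T + t, f) = X(best, f);
        argmax(b * T + t, f) = best;
      }
    }
  }
  return out;
}

mat dropout_mask(Rng& rng, uword r, uword c, double p) {
  mat m(r, c);
  double keep = 1.0 - p;
  for (uword j = 0; j < c; ++j)
    for (uword i = 0; i < r; ++i)
      m(i, j) = (rng.unif() < keep) ? (1.0 / keep) : 0.0;
  return m;
}

struct Adam {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const std::vector<mat*>& params) {
    for (auto* p : params) {
      m.emplace_back(p->n_rows, p->n_cols, fill::zeros);
      v.emplace_back(p->n_rows, p->n_cols, fill::zeros);
    }
  }
  // AdamW: decoupled weight decay (wd = 0 reduces to Adam)
  void step(std::vector<mat*>& params, const std::vector<mat*>& grads,
            double lr, double wd, const std::vector<bool>& decay) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * (*grads[i]);
      v[i] = b2 * v[i] + (1 - b2) * square(*grads[i]);
      mat upd = (m[i] / c1) / (sqrt(v[i] / c2) + eps);
      if (wd > 0 && decay[i]) upd += wd * (*params[i]);
      *params[i] -= lr * upd;
    }
  }
};

inline mat relu(const mat& x) { return clamp(x, 0.0, datum::inf); }

vec sigmoid_vec(const vec& z) { return 1.0 / (1.0 + exp(-z)); }

// Gather a batch (T x C x n cube -> (T*B x C) matrix).
mat gather_batch(const cube& X, const std::vector<uword>& idx,
                 uword lo, uword hi) {
  uword T = X.n_rows, C = X.n_cols, B = hi - lo;
  mat out(T * B, C);
  for (uword b = 0; b < B; ++b)
    out.rows(b * T, b * T + T - 1) = X.slice(idx[lo + b]);
  return out;
}

}  // namespace

// ---------------------------------------------------------------------------
// CNN: 3 x [conv(k, ReLU) -> maxpool(2) -> dropout] -> flatten -> dropout ->
// dense(10, ReLU) -> dense(1, sigmoid); AdamW; weighted BCE.
// ---------------------------------------------------------------------------

struct CnnParams {
  mat W1, W2, W3, Wd, Wo;
  mat b1, b2, b3, bd, bo;  // row vectors
};

static CnnParams cnn_init(Rng& rng, uword C, const ivec& ks, const ivec& nf,
                          uword dense_units, uword flat_dim) {
  CnnParams P;
  P.W1 = glorot(rng, ks[0] * C, nf[0], ks[0] * C, nf[0]);
  P.b1 = mat(1, nf[0], fill::zeros);
  P.W2 = glorot(rng, ks[1] * nf[0], nf[1], ks[1] * nf[0], nf[1]);
  P.b2 = mat(1, nf[1], fill::zeros);
  P.W3 = glorot(rng, ks[2] * nf[1], nf[2], ks[2] * nf[1], nf[2]);
  P.b3 = mat(1, nf[2], fill::zeros);
  P.Wd = glorot(rng, flat_dim, dense_units, flat_dim, dense_units);
  P.bd = mat(1, dense_units, fill::zeros);
  P.Wo = glorot(rng, dense_units, 1, dense_units, 1);
  P.bo = mat(1, 1, fill::zeros);
  return P;
}

// Flatten (T*B x F) -> (B x T*F) in (t fastest within feature) order.
static mat flatten_tb(const mat& X, uword T, uword B) {
  uword F = X.n_cols;
  mat out(B, T * F);
  for (uword b = 0; b < B; ++b) {
    for (uword f = 0; f < F; ++f)
      out.row(b).subvec(f * T, f * T + T - 1) =
          X.col(f).subvec(b * T, b * T + T - 1).t();
  }
  return out;
}

static mat unflatten_tb(const mat& G, uword T, uword B, uword F) {
  mat out(T * B, F);
  for (uword b = 0; b < B; ++b)
    for (uword f = 0; f < F; ++f)
      out.col(f).subvec(b * T, b * T + T - 1) =
          G.row(b).subvec(f * T, f * T + T - 1).t();
  return out;
}

static vec cnn_forward(const CnnParams& P, const mat& Xb, uword T, uword B,
                       const ivec& ks) {
  int p1 = (ks[0] - 1) / 2, p2 = (ks[1] - 1) / 2, p3 = (ks[2] - 1) / 2;
  mat A1 = relu(im2col(Xb, T, B, ks[0], p1) * P.W1 + repmat(P.b1, T * B, 1));
  PoolCache c1; mat P1 = maxpool(A1, T, B, 2, c1);
  uword T2 = T / 2;
  mat A2 = relu(im2col(P1, T2, B, ks[1], p2) * P.W2 + repmat(P.b2, T2 * B, 1));
  PoolCache c2; mat P2 = maxpool(A2, T2, B, 2, c2);
  uword T3 = T2 / 2;
  mat A3 = relu(im2col(P2, T3, B, ks[2], p3) * P.W3 + repmat(P.b3, T3 * B, 1));
  PoolCache c3; mat P3 = maxpool(A3, T3, B, 2, c3);
  uword T4 = T3 / 2;
  mat flat = flatten_tb(P3, T4, B);
  mat H = relu(flat * P.Wd + repmat(P.bd, B, 1));
  vec z = H * P.Wo + repmat(P.bo, B, 1);
  return sigmoid_vec(z);
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(const arma::cube& X, const arma::vec& y,
                         const arma::vec& sample_w,
                         Rcpp::IntegerVector kernel_sizes,
                         Rcpp::IntegerVector n_filters,
                         int dense_units, double dropout, int epochs,
                         double lr, int batch_size, double weight_decay,
                         int seed) {
  uword T = X.n_rows, C = X.n_cols, N = X.n_slices;
  ivec ks = {kernel_sizes[0], kernel_sizes[1], kernel_sizes[2]};
  ivec nf = {n_filters[0], n_filters[1], n_filters[2]};
  uword T4 = T / 8;
  uword flat_dim = T4 * nf[2];
  Rng rng((unsigned int)seed);
  CnnParams P = cnn_init(rng, C, ks, nf, dense_units, flat_dim);

  std::vector<mat*> params = {&P.W1, &P.b1, &P.W2, &P.b2, &P.W3, &P.b3,
                              &P.Wd, &P.bd, &P.Wo, &P.bo};
  std::vector<bool> decay = {true, false, true, false, true, false,
                             true, false, true, false};
  Adam opt; opt.init(params);

  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;
  int p1 = (ks[0] - 1) / 2, p2 = (ks[1] - 1) / 2, p3 = (ks[2] - 1) / 2;

  for (int ep = 0; ep < epochs; ++ep) {
    rng.shuffle(order);
    for (uword lo = 0; lo < N; lo += batch_size) {
      uword hi = std::min(N, lo + (uword)batch_size);
      uword B = hi - lo;
      mat Xb = gather_batch(X, order, lo, hi);
      vec yb(B), wb(B);
      for (uword b = 0; b < B; ++b) {
        yb[b] = y[order[lo + b]];
        wb[b] = sample_w[order[lo + b]];
      }
      // forward with caches
      mat cols1 = im2col(Xb, T, B, ks[0], p1);
      mat Z1 = cols1 * P.W1 + repmat(P.b1, T * B, 1);
      mat A1 = relu(Z1);
      PoolCache c1; mat P1 = maxpool(A1, T, B, 2, c1);
      uword T2 = T / 2;
      mat M1 = dropout_mask(rng, P1.n_rows, P1.n_cols, dropout);
      mat D1 = P1 % M1;
      mat cols2 = im2col(D1, T2, B, ks[1], p2);
      mat Z2 = cols2 * P.W2 + repmat(P.b2, T2 * B, 1);
      mat A2 = relu(Z2);
      PoolCache c2; mat P2m = maxpool(A2, T2, B, 2, c2);
      uword T3 = T2 / 2;
      mat M2 = dropout_mask(rng, P2m.n_rows, P2m.n_cols, dropout);
      mat D2 = P2m % M2;
      mat cols3 = im2col(D2, T3, B, ks[2], p3);
      mat Z3 = cols3 * P.W3 + repmat(P.b3, T3 * B, 1);
      mat A3 = relu(Z3);
      PoolCache c3; mat P3m = maxpool(A3, T3, B, 2, c3);
      mat M3 = dropout_mask(rng, P3m.n_rows, P3m.n_cols, dropout);
      mat D3 = P3m % M3;
      mat flat = flatten_tb(D3, T4, B);
      mat M4 = dropout_mask(rng, flat.n_rows, flat.n_cols, dropout);
      mat D4 = flat % M4;
      mat Zd = D4 * P.Wd + repmat(P.bd, B, 1);
      mat H = relu(Zd);
      vec z = H * P.Wo + repmat(P.bo, B, 1);
      vec p = sigmoid_vec(z);

      // weighted BCE gradient wrt logit
      vec dz = wb % (p - yb) / (double)B;
      mat dWo = H.t() * dz;
      mat dbo(1, 1); dbo(0, 0) = accu(dz);
      mat dH = dz * P.Wo.t();
      mat dZd = dH % conv_to<mat>::from(Zd > 0);
      mat dWd = D4.t() * dZd;
      mat dbd = sum(dZd, 0);
      mat dD4 = dZd * P.Wd.t();
      mat dflat = dD4 % M4;
      mat dD3 = unflatten_tb(dflat, T4, B, nf[2]);
      mat dP3 = dD3 % M3;
      mat dA3 = maxpool_backward(dP3, T3, B, c3);
      mat dZ3 = dA3 % conv_to<mat>::from(Z3 > 0);
      mat dW3 = cols3.t() * dZ3;
      mat db3 = sum(dZ3, 0);
      mat dcols3 = dZ3 * P.W3.t();
      mat dD2(T3 * B, D2.n_cols, fill::zeros);
      col2im_add(dD2, dcols3, T3, B, ks[2], p3);
      mat dP2 = dD2 % M2;
      mat dA2 = maxpool_backward(dP2, T2, B, c2);
      mat dZ2 = dA2 % conv_to<mat>::from(Z2 > 0);
      mat dW2 = cols2.t() * dZ2;
      mat db2 = sum(dZ2, 0);
      mat dcols2 = dZ2 * P.W2.t();
      mat dD1(T2 * B, D1.n_cols, fill::zeros);
      col2im_add(dD1, dcols2, T2, B, ks[1], p2);
      mat dP1 = dD1 % M1;
      mat dA1 = maxpool_backward(dP1, T, B, c1);
      mat dZ1 = dA1 % conv_to<mat>::from(Z1 > 0);
      mat dW1 = cols1.t() * dZ1;
      mat db1 = sum(dZ1, 0);

      std::vector<mat*> grads = {&dW1, &db1, &dW2, &db2, &dW3, &db3,
                                 &dWd, &dbd, &dWo, &dbo};
      opt.step(params, grads, lr, weight_decay, decay);
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("W1") = P.W1, Rcpp::Named("b1") = P.b1,
      Rcpp::Named("W2") = P.W2, Rcpp::Named("b2") = P.b2,
      Rcpp::Named("W3") = P.W3, Rcpp::Named("b3") = P.b3,
      Rcpp::Named("Wd") = P.Wd, Rcpp::Named("bd") = P.bd,
      Rcpp::Named("Wo") = P.Wo, Rcpp::Named("bo") = P.bo);
}

// [[Rcpp::export]]
arma::vec cpp_cnn_predict(Rcpp::List state, const arma::cube& X,
                          Rcpp::IntegerVector kernel_sizes, int batch_size) {
  CnnParams P;
  P.W1 = Rcpp::as<mat>(state["W1"]); P.b1 = Rcpp::as<mat>(state["b1"]);
  P.W2 = Rcpp::as<mat>(state["W2"]); P.b2 = Rcpp::as<mat>(state["b2"]);
  P.W3 = Rcpp::as<mat>(state["W3"]); P.b3 = Rcpp::as<mat>(state["b3"]);
  P.Wd = Rcpp::as<mat>(state["Wd"]); P.bd = Rcpp::as<mat>(state["bd"]);
  P.Wo = Rcpp::as<mat>(state["Wo"]); P.bo = Rcpp::as<mat>(state["bo"]);
  ivec ks = {kernel_sizes[0], kernel_sizes[1], kernel_sizes[2]};
  uword T = X.n_rows, N = X.n_slices;
  vec out(N);
  std::vector<uword> idx(N);
  for (uword i = 0; i < N; ++i) idx[i] = i;
  for (uword lo = 0; lo < N; lo += batch_size) {
    uword hi = std::min(N, lo + (uword)batch_size);
    mat Xb = gather_batch(X, idx, lo, hi);
    out.subvec(lo, hi - 1) = cnn_forward(P, Xb, T, hi - lo, ks);
  }
  return out;
}

// ---------------------------------------------------------------------------
// InceptionTime member network.
// ---------------------------------------------------------------------------

struct BnParams { mat gamma, beta, run_mean, run_var; };

struct BnCache { mat xhat; rowvec mean, invstd; };

static mat bn_forward_train(BnParams& bn, const mat& X, BnCache& cache,
                            double momentum = 0.9, double eps = 1e-5) {
  rowvec mu = mean(X, 0);
  rowvec var = mean(square(X.each_row() - mu), 0);
  cache.mean = mu;
  cache.invstd = 1.0 / sqrt(var + eps);
  cache.xhat = (X.each_row() - mu).each_row() % cache.invstd;
  bn.run_mean = momentum * bn.run_mean + (1 - momentum) * mu;
  bn.run_var = momentum * bn.run_var + (1 - momentum) * var;
  return (cache.xhat.each_row() % bn.gamma.row(0)).each_row() + bn.beta.row(0);
}

static mat bn_forward_eval(const BnParams& bn, const mat& X, double eps = 1e-5) {
  rowvec invstd = 1.0 / sqrt(bn.run_var.row(0) + eps);
  mat xhat = (X.each_row() - bn.run_mean.row(0)).each_row() % invstd;
  return (xhat.each_row() % bn.gamma.row(0)).each_row() + bn.beta.row(0);
}

static mat bn_backward(const BnParams& bn, const BnCache& cache, const mat& dY,
                       mat& dgamma, mat& dbeta) {
  double n = (double)dY.n_rows;
  dgamma = sum(dY % cache.xhat, 0);
  dbeta = sum(dY, 0);
  mat dxhat = dY.each_row() % bn.gamma.row(0);
  rowvec s1 = sum(dxhat, 0);
  rowvec s2 = sum(dxhat % cache.xhat, 0);
  mat dX = dxhat;
  dX.each_row() -= s1 / n;
  dX -= cache.xhat.each_row() % (s2 / n);
  dX.each_row() %= cache.invstd;
  return dX;
}

struct IncModule {
  mat Wb;           // bottleneck 1x1: (Cin x Bn)
  mat Wk2, Wk4, Wk8;  // branch convs: (k*Bn x F)
  mat Wp;           // pool-branch 1x1: (Cin x F)
  BnParams bn;
};

struct IncNet {
  std::vector<IncModule> mods;
  mat Ws1, Ws2;       // residual shortcut 1x1 convs
  BnParams bns1, bns2;
  mat Wh, bh;         // head dense
  int depth, Bn, F;
  ivec ks;
};

static BnParams bn_init(uword C) {
  BnParams bn;
  bn.gamma = mat(1, C, fill::ones);
  bn.beta = mat(1, C, fill::zeros);
  bn.run_mean = mat(1, C, fill::zeros);
  bn.run_var = mat(1, C, fill::ones);
  return bn;
}

static IncNet inception_init(Rng& rng, uword C, int depth, int bottleneck,
                             int filters, const ivec& ks) {
  IncNet net;
  net.depth = depth; net.Bn = bottleneck; net.F = filters; net.ks = ks;
  uword Cin = C;
  uword Cout = 4 * (uword)filters;
  for (int d = 0; d < depth; ++d) {
    IncModule m;
    m.Wb = glorot(rng, Cin, bottleneck, Cin, bottleneck);
    m.Wk2 = glorot(rng, ks[0] * bottleneck, filters, ks[0] * bottleneck, filters);
    m.Wk4 = glorot(rng, ks[1] * bottleneck, filters, ks[1] * bottleneck, filters);
    m.Wk8 = glorot(rng, ks[2] * bottleneck, filters, ks[2] * bottleneck, filters);
    m.Wp = glorot(rng, Cin, filters, Cin, filters);
    m.bn = bn_init(Cout);
    net.mods.push_back(std::move(m));
    Cin = Cout;
  }
  net.Ws1 = glorot(rng, C, Cout, C, Cout);
  net.bns1 = bn_init(Cout);
  net.Ws2 = glorot(rng, Cout, Cout, Cout, Cout);
  net.bns2 = bn_init(Cout);
  net.Wh = glorot(rng, Cout, 1, Cout, 1);
  net.bh = mat(1, 1, fill::zeros);
  return net;
}

struct IncModCache {
  mat in, bott, cols2, cols4, cols8, pooled, concat_pre_bn;
  umat pool_arg;
  BnCache bn;
  mat relu_in;  // value whose positive part defines the ReLU derivative
};

struct IncFwdCache {
  std::vector<IncModCache> mods;
  mat res0;          // network input (residual source 1)
  mat res3;          // output of module 3 (residual source 2)
  BnCache bns1, bns2;
  mat short1_pre, short2_pre;
  mat gap;           // (B x Cout)
  vec z;
};

static int same_pad(int k) { return (k - 1) / 2; }

static mat inception_forward(IncNet& net, const mat& X0, uword T, uword B,
                             bool train, IncFwdCache* cache) {
  mat x = X0;
  mat res_in = X0;
  if (cache) cache->res0 = X0;
  uword Cout = 4 * (uword)net.F;
  for (int d = 0; d < net.depth; ++d) {
    IncModule& m = net.mods[d];
    IncModCache mc;
    if (cache) mc.in = x;
    mat bott = x * m.Wb;
    mat c2 = im2col(bott, T, B, net.ks[0], same_pad(net.ks[0]));
    mat c4 = im2col(bott, T, B, net.ks[1], same_pad(net.ks[1]));
    mat c8 = im2col(bott, T, B, net.ks[2], same_pad(net.ks[2]));
    umat parg;
    mat pooled = maxpool3_same(x, T, B, parg);
    mat cat(T * B, Cout);
    cat.cols(0, net.F - 1) = c2 * m.Wk2;
    cat.cols(net.F, 2 * net.F - 1) = c4 * m.Wk4;
    cat.cols(2 * net.F, 3 * net.F - 1) = c8 * m.Wk8;
    cat.cols(3 * net.F, 4 * net.F - 1) = pooled * m.Wp;
    mat h;
    BnCache bc;
    if (train) h = bn_forward_train(m.bn, cat, bc);
    else h = bn_forward_eval(m.bn, cat);
    bool residual = (d == 2 || d == net.depth - 1);
    if (residual) {
      mat& Ws = (d == 2) ? net.Ws1 : net.Ws2;
      BnParams& bns = (d == 2) ? net.bns1 : net.bns2;
      mat spre = res_in * Ws;
      mat sh;
      BnCache sbc;
      if (train) sh = bn_forward_train(bns, spre, sbc);
      else sh = bn_forward_eval(bns, spre);
      h += sh;
      if (cache) {
        if (d == 2) { cache->bns1 = sbc; cache->short1_pre = spre; }
        else { cache->bns2 = sbc; cache->short2_pre = spre; }
      }
    }
    mat out = relu(h);
    if (cache) {
      mc.bott = bott; mc.cols2 = c2; mc.cols4 = c4; mc.cols8 = c8;
      mc.pooled = pooled; mc.pool_arg = parg; mc.bn = bc;
      mc.concat_pre_bn = cat; mc.relu_in = h;
      cache->mods.push_back(std::move(mc));
    }
    if (residual) {
      if (d == 2 && cache) cache->res3 = out;
      res_in = out;
    }
    x = out;
  }
  // global average pooling over time
  mat gap(B, Cout);
  for (uword b = 0; b < B; ++b)
    gap.row(b) = mean(x.rows(b * T, b * T + T - 1), 0);
  if (cache) cache->gap = gap;
  return gap;
}

// [[Rcpp::export]]
Rcpp::List cpp_inception_train(const arma::cube& X, const arma::vec& y,
                               const arma::vec& sample_w, int depth,
                               int bottleneck, int filters,
                               Rcpp::IntegerVector kernel_sizes, int epochs,
                               double lr, int batch_size, double weight_decay,
                               int seed) {
  uword T = X.n_rows, C = X.n_cols, N = X.n_slices;
  ivec ks = {kernel_sizes[0], kernel_sizes[1], kernel_sizes[2]};
  Rng rng((unsigned int)seed);
  IncNet net = inception_init(rng, C, depth, bottleneck, filters, ks);
  uword Cout = 4 * (uword)filters;

  std::vector<mat*> params;
  std::vector<bool> decay;
  for (auto& m : net.mods) {
    params.insert(params.end(), {&m.Wb, &m.Wk2, &m.Wk4, &m.Wk8, &m.Wp,
                                 &m.bn.gamma, &m.bn.beta});
    decay.insert(decay.end(), {true, true, true, true, true, false, false});
  }
  params.insert(params.end(), {&net.Ws1, &net.bns1.gamma, &net.bns1.beta,
                               &net.Ws2, &net.bns2.gamma, &net.bns2.beta,
                               &net.Wh, &net.bh});
  decay.insert(decay.end(), {true, false, false, true, false, false,
                             true, false});
  Adam opt; opt.init(params);

  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    rng.shuffle(order);
    for (uword lo = 0; lo < N; lo += batch_size) {
      uword hi = std::min(N, lo + (uword)batch_size);
      uword B = hi - lo;
      mat Xb = gather_batch(X, order, lo, hi);
      vec yb(B), wb(B);
      for (uword b = 0; b < B; ++b) {
        yb[b] = y[order[lo + b]];
        wb[b] = sample_w[order[lo + b]];
      }
      IncFwdCache cache;
      mat gap = inception_forward(net, Xb, T, B, true, &cache);
      vec z = gap * net.Wh + repmat(net.bh, B, 1);
      vec p = sigmoid_vec(z);
      vec dz = wb % (p - yb) / (double)B;

      mat dWh = gap.t() * dz;
      mat dbh(1, 1); dbh(0, 0) = accu(dz);
      mat dgap = dz * net.Wh.t();
      // un-GAP: spread gradient uniformly over time
      mat dx(T * B, Cout);
      for (uword b = 0; b < B; ++b)
        dx.rows(b * T, b * T + T - 1) = repmat(dgap.row(b) / (double)T, T, 1);

      std::vector<mat> grads_store(params.size());
      for (size_t i = 0; i < params.size(); ++i)
        grads_store[i] = mat(params[i]->n_rows, params[i]->n_cols, fill::zeros);
      // map param pointer -> index
      auto gidx = [&](mat* p) {
        for (size_t i = 0; i < params.size(); ++i)
          if (params[i] == p) return i;
        Rcpp::stop("internal: unknown parameter");
        return (size_t)0;
      };

      mat dres_pending;  // gradient flowing to an earlier residual source
      bool res3_used = false;
      mat dres0(T * B, C, fill::zeros);

      for (int d = net.depth - 1; d >= 0; --d) {
        IncModule& m = net.mods[d];
        IncModCache& mc = cache.mods[d];
        bool residual = (d == 2 || d == net.depth - 1);
        // gradient arriving at this module's ReLU output
        if (d == 2 && res3_used) dx += dres_pending;
        mat dh = dx % conv_to<mat>::from(mc.relu_in > 0);
        if (residual) {
          mat& Ws = (d == 2) ? net.Ws1 : net.Ws2;
          BnParams& bns = (d == 2) ? net.bns1 : net.bns2;
          BnCache& sbc = (d == 2) ? cache.bns1 : cache.bns2;
          mat dg, db;
          mat dspre = bn_backward(bns, sbc, dh, dg, db);
          grads_store[gidx(&bns.gamma)] += dg;
          grads_store[gidx(&bns.beta)] += db;
          const mat& src = (d == 2) ? cache.res0 : cache.res3;
          grads_store[gidx(&Ws)] += src.t() * dspre;
          mat dsrc = dspre * Ws.t();
          if (d == 2) {
            dres0 += dsrc;
          } else {
            dres_pending = dsrc;  // flows to module-3 output
            res3_used = true;
          }
        }
        mat dg, db;
        mat dcat = bn_backward(m.bn, mc.bn, dh, dg, db);
        grads_store[gidx(&m.bn.gamma)] += dg;
        grads_store[gidx(&m.bn.beta)] += db;

        mat d2 = dcat.cols(0, net.F - 1);
        mat d4 = dcat.cols(net.F, 2 * net.F - 1);
        mat d8 = dcat.cols(2 * net.F, 3 * net.F - 1);
        mat dp = dcat.cols(3 * net.F, 4 * net.F - 1);

        grads_store[gidx(&m.Wk2)] += mc.cols2.t() * d2;
        grads_store[gidx(&m.Wk4)] += mc.cols4.t() * d4;
        grads_store[gidx(&m.Wk8)] += mc.cols8.t() * d8;
        grads_store[gidx(&m.Wp)] += mc.pooled.t() * dp;

        mat dbott(T * B, net.Bn, fill::zeros);
        col2im_add(dbott, d2 * m.Wk2.t(), T, B, ks[0], same_pad(ks[0]));
        col2im_add(dbott, d4 * m.Wk4.t(), T, B, ks[1], same_pad(ks[1]));
        col2im_add(dbott, d8 * m.Wk8.t(), T, B, ks[2], same_pad(ks[2]));
        grads_store[gidx(&m.Wb)] += mc.in.t() * dbott;

        mat din = dbott * m.Wb.t();
        // pool branch input gradient
        mat dpool_in(T * B, mc.in.n_cols, fill::zeros);
        mat dpooled = dp * m.Wp.t();
        for (uword f = 0; f < dpool_in.n_cols; ++f)
          for (uword i = 0; i < dpooled.n_rows; ++i)
            dpool_in(mc.pool_arg(i, f), f) += dpooled(i, f);
        din += dpool_in;
        dx = din;
      }
      dx += dres0;  // unused further; input has no parameters

      std::vector<mat*> grads;
      for (auto& g : grads_store) grads.push_back(&g);
      opt.step(params, grads, lr, weight_decay, decay);
    }
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List mods(net.depth);
  for (int d = 0; d < net.depth; ++d) {
    IncModule& m = net.mods[d];
    mods[d] = Rcpp::List::create(
        Rcpp::Named("Wb") = m.Wb, Rcpp::Named("Wk2") = m.Wk2,
        Rcpp::Named("Wk4") = m.Wk4, Rcpp::Named("Wk8") = m.Wk8,
        Rcpp::Named("Wp") = m.Wp, Rcpp::Named("gamma") = m.bn.gamma,
        Rcpp::Named("beta") = m.bn.beta,
        Rcpp::Named("run_mean") = m.bn.run_mean,
        Rcpp::Named("run_var") = m.bn.run_var);
  }
  return Rcpp::List::create(
      Rcpp::Named("modules") = mods,
      Rcpp::Named("Ws1") = net.Ws1,
      Rcpp::Named("bns1") = Rcpp::List::create(
          Rcpp::Named("gamma") = net.bns1.gamma, Rcpp::Named("beta") = net.bns1.beta,
          Rcpp::Named("run_mean") = net.bns1.run_mean,
          Rcpp::Named("run_var") = net.bns1.run_var),
      Rcpp::Named("Ws2") = net.Ws2,
      Rcpp::Named("bns2") = Rcpp::List::create(
          Rcpp::Named("gamma") = net.bns2.gamma, Rcpp::Named("beta") = net.bns2.beta,
          Rcpp::Named("run_mean") = net.bns2.run_mean,
          Rcpp::Named("run_var") = net.bns2.run_var),
      Rcpp::Named("Wh") = net.Wh, Rcpp::Named("bh") = net.bh);
}

static BnParams bn_from_list(Rcpp::List l) {
  BnParams bn;
  bn.gamma = Rcpp::as<mat>(l["gamma"]);
  bn.beta = Rcpp::as<mat>(l["beta"]);
  bn.run_mean = Rcpp::as<mat>(l["run_mean"]);
  bn.run_var = Rcpp::as<mat>(l["run_var"]);
  return bn;
}

// [[Rcpp::export]]
arma::vec cpp_inception_predict(Rcpp::List state, const arma::cube& X,
                                int depth, int bottleneck, int filters,
                                Rcpp::IntegerVector kernel_sizes,
                                int batch_size) {
  ivec ks = {kernel_sizes[0], kernel_sizes[1], kernel_sizes[2]};
  IncNet net;
  net.depth = depth; net.Bn = bottleneck; net.F = filters; net.ks = ks;
  Rcpp::List mods = state["modules"];
  for (int d = 0; d < depth; ++d) {
    Rcpp::List l = mods[d];
    IncModule m;
    m.Wb = Rcpp::as<mat>(l["Wb"]);
    m.Wk2 = Rcpp::as<mat>(l["Wk2"]);
    m.Wk4 = Rcpp::as<mat>(l["Wk4"]);
    m.Wk8 = Rcpp::as<mat>(l["Wk8"]);
    m.Wp = Rcpp::as<mat>(l["Wp"]);
    m.bn = bn_from_list(Rcpp::List::create(
        Rcpp::Named("gamma") = l["gamma"], Rcpp::Named("beta") = l["beta"],
        Rcpp::Named("run_mean") = l["run_mean"],
        Rcpp::Named("run_var") = l["run_var"]));
    net.mods.push_back(std::move(m));
  }
  net.Ws1 = Rcpp::as<mat>(state["Ws1"]);
  net.bns1 = bn_from_list(state["bns1"]);
  net.Ws2 = Rcpp::as<mat>(state["Ws2"]);
  net.bns2 = bn_from_list(state["bns2"]);
  net.Wh = Rcpp::as<mat>(state["Wh"]);
  net.bh = Rcpp::as<mat>(state["bh"]);

  uword T = X.n_rows, N = X.n_slices;
  vec out(N);
  std::vector<uword> idx(N);
  for (uword i = 0; i < N; ++i) idx[i] = i;
  for (uword lo = 0; lo < N; lo += batch_size) {
    uword hi = std::min(N, lo + (uword)batch_size);
    uword B = hi - lo;
    mat Xb = gather_batch(X, idx, lo, hi);
    mat gap = inception_forward(net, Xb, T, B, false, nullptr);
    vec z = gap * net.Wh + repmat(net.bh, B, 1);
    out.subvec(lo, hi - 1) = sigmoid_vec(z);
  }
  return out;
}
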