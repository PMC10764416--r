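// MiniRocket transform: dilated two-valued convolutions (length 9, weights
// -1 with three taps of +2) pooled by the proportion of positive values
// (PPV) against fitted bias quantiles. "Same" zero padding throughout, so
// every kernel/dilation produces one pooled value per bias over the full
// window length.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Convolution of the summed channel series for every kernel at one dilation.
// x: (T x C) window; chans: 0-based channel subset; positions: (84 x 3)
// 0-based high-weight tap positions. Returns (T x 84).
mat mr_conv_all(const mat& x, const uvec& chans, const imat& positions,
                int dilation) {
  uword T = x.n_rows;
  vec xc(T, fill::zeros);
  for (uword i = 0; i < chans.n_elem; ++i) xc += x.col(chans[i]);
  // z(t, j) = xc[t + (j - 4) * dilation], zero-padded
  mat z(T, 9, fill::zeros);
  for (int j = 0; j < 9; ++j) {
    int off = (j - 4) * dilation;
    int t0 = std::max(0, -off), t1 = (int)T - 1 - std::max(0, off);
    if (t1 >= t0)
      z.col(j).subvec(t0, t1) = xc.subvec(t0 + off, t1 + off);
  }
  vec base = -sum(z, 1);
  mat out(T, positions.n_rows);
  for (uword k = 0; k < positions.n_rows; ++k) {
    out.col(k) = base + 3.0 * (z.col(positions(k, 0)) + z.col(positions(k, 1)) +
                               z.col(positions(k, 2)));
  }
  return out;
}

}  // namespace

// Fit biases: for each (dilation, kernel, bias slot) take the given quantile
// of the convolution output on one designated training window.
// window_choice and quantiles are laid out kernel-fastest then bias slot:
// for dilation d (0-based), kernel k, slot s the flat index is
// offset[d] + s * 84 + k, with offset[d] = 84 * sum(n_feat[0..d-1]).
// chan_combo: (n_dilations x 84) list index into `combos`.
// [[Rcpp::export]]
arma::vec cpp_mr_fit_biases(const arma::cube& X, const arma::imat& positions,
                            const arma::ivec& dilations,
                            const arma::ivec& n_feat_per_dilation,
                            Rcpp::List combos, const arma::ivec& combo_index,
                            const arma::ivec& window_choice,
                            const arma::vec& quantiles) {
  uword n_dil = dilations.n_elem, n_kern = positions.n_rows;
  uword total = 0;
  for (uword d = 0; d < n_dil; ++d) total += n_kern * n_feat_per_dilation[d];
  vec biases(total);
  uword offset = 0;
  for (uword d = 0; d < n_dil; ++d) {
    uword nf = n_feat_per_dilation[d];
    for (uword k = 0; k < n_kern; ++k) {
      uvec chans = Rcpp::as<uvec>(combos[combo_index[d * n_kern + k]]);
      imat pos1 = positions.row(k);
      for (uword s = 0; s < nf; ++s) {
        uword flat = offset + s * n_kern + k;
        const mat& xw = X.slice(window_choice[flat]);
        mat conv = mr_conv_all(xw, chans, pos1, dilations[d]);
        vec v = sort(conv.col(0));
        double q = quantiles[flat];
        // linear-interpolation quantile (type 7)
        double h = q * (v.n_elem - 1);
        uword lo = (uword)std::floor(h);
        uword hi = std::min(v.n_elem - 1, lo + 1);
        biases[flat] = v[lo] + (h - lo) * (v[hi] - v[lo]);
      }
      Rcpp::checkUserInterrupt();
    }
    offset += n_kern * nf;
  }
  return biases;
}

// PPV feature matrix: (n_windows x total_features), features laid out as in
// cpp_mr_fit_biases. Per (window, dilation) the 9 shifted copies and their
// negated sum are precomputed once per channel and shared across kernels;
// PPVs against the (sorted) bias set are read off a sorted copy of the
// convolution output.
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_mr_transform(const arma::cube& X,
                                     const arma::imat& positions,
                                     const arma::ivec& dilations,
                                     const arma::ivec& n_feat_per_dilation,
                                     Rcpp::List combos,
                                     const arma::ivec& combo_index,
                                     const arma::vec& biases) {
  uword N = X.n_slices, n_dil = dilations.n_elem, n_kern = positions.n_rows;
  uword T = X.n_rows, C = X.n_cols;
  uword total = biases.n_elem;
  // fill the R matrix directly: at ~10^4 features x 10^4 windows an extra
  // arma -> R copy would double the peak footprint
  Rcpp::NumericMatrix out((int)N, (int)total);
  std::vector<uvec> combo_vec(combos.size());
  for (int i = 0; i < combos.size(); ++i)
    combo_vec[i] = Rcpp::as<uvec>(combos[i]);

  for (uword w = 0; w < N; ++w) {
    const mat& xw = X.slice(w);
    uword offset = 0;
    for (uword d = 0; d < n_dil; ++d) {
      int dil = dilations[d];
      uword nf = n_feat_per_dilation[d];
      // per-channel shifted copies z_c(t, j) and base_c(t) = -sum_j z_c(t, j)
      cube z(T, 9, C, fill::zeros);
      mat base(T, C);
      for (uword c = 0; c < C; ++c) {
        for (int j = 0; j < 9; ++j) {
          int off = (j - 4) * dil;
          int t0 = std::max(0, -off), t1 = (int)T - 1 - std::max(0, off);
          if (t1 >= t0)
            z.slice(c).col(j).subvec(t0, t1) = xw.col(c).subvec(t0 + off, t1 + off);
        }
        base.col(c) = -sum(z.slice(c), 1);
      }
      for (uword k = 0; k < n_kern; ++k) {
        const uvec& chans = combo_vec[combo_index[d * n_kern + k]];
        int p0 = positions(k, 0), p1 = positions(k, 1), p2 = positions(k, 2);
        vec cv(T, fill::zeros);
        double* cvw = cv.memptr();
        for (uword i = 0; i < chans.n_elem; ++i) {
          uword c = chans[i];
          const double* bs = base.colptr(c);
          const double* z0 = z.slice(c).colptr(p0);
          const double* z1 = z.slice(c).colptr(p1);
          const double* z2 = z.slice(c).colptr(p2);
          for (uword t = 0; t < T; ++t)
            cvw[t] += bs[t] + 3.0 * (z0[t] + z1[t] + z2[t]);
        }
        const double* cvp = cv.memptr();
        for (uword s = 0; s < nf; ++s) {
          uword flat = offset + s * n_kern + k;
          double b = biases[flat];
          int cnt = 0;  // branchless count of values strictly above the bias
          for (uword t = 0; t < T; ++t) cnt += (cvp[t] > b);
          out((int)w, (int)flat) = (double)cnt / (double)T;
        }
      }
      offset += n_kern * nf;
    }
    if (w % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Column-wise (x - mu) / sd, modifying X in place. The caller owns the only
// reference; avoids duplicating large feature matrices.
// [[Rcpp::export]]
void cpp_standardize_inplace(Rcpp::NumericMatrix X, const arma::vec& mu,
                             const arma::vec& sd) {
  int n = X.nrow(), p = X.ncol();
  for (int j = 0; j < p; ++j) {
    double m = mu[j], s = sd[j];
    double* col = &X(0, j);
    for (int i = 0; i < n; ++i) col[i] = (col[i] - m) / s;
  }
}
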