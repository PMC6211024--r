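// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// 1-D "same" convolution (stride 1, odd kernel, zero padding) on
// channels-first (C, L, B) tensors. Weights are stored as a (k*C, F) matrix
// whose rows are ordered channel-fastest, tap-slowest, so the forward pass
// is one im2col gather plus one BLAS product. Everything memory-bound stays
// on the C++ side; BLAS does the arithmetic.

static void im2col(const double* xp, double* cols, int C, int L, int B, int k) {
  // xp: (C, L + k - 1, B) zero-padded; cols: (k*C, L*B)
  const int Lp = L + k - 1;
  const std::size_t kc = static_cast<std::size_t>(k) * C;
  std::size_t col = 0;
  for (int b = 0; b < B; ++b) {
    const double* base = xp + static_cast<std::size_t>(b) * C * Lp;
    for (int t = 0; t < L; ++t, ++col)
      std::copy(base + static_cast<std::size_t>(t) * C,
                base + static_cast<std::size_t>(t) * C + kc,
                cols + col * kc);
  }
}

static arma::mat pad_tensor(const NumericVector& X, int C, int L, int B, int P) {
  const int Lp = L + 2 * P;
  arma::mat Xp(static_cast<arma::uword>(C) * Lp, B, arma::fill::zeros);
  const double* x = X.begin();
  for (int b = 0; b < B; ++b)
    std::copy(x + static_cast<std::size_t>(b) * C * L,
              x + static_cast<std::size_t>(b + 1) * C * L,
              Xp.colptr(b) + static_cast<std::size_t>(P) * C);
  return Xp;
}

// [[Rcpp::export]]
NumericVector conv1d_fwd(const NumericVector& X, const NumericMatrix& W,
                         const NumericVector& bias, int k) {
  IntegerVector d = X.attr("dim");
  const int C = d[0], L = d[1], B = d[2], P = (k - 1) / 2;
  const int F = W.ncol();
  arma::mat Xp = pad_tensor(X, C, L, B, P);
  arma::mat cols(static_cast<arma::uword>(k) * C,
                 static_cast<arma::uword>(L) * B);
  im2col(Xp.memptr(), cols.memptr(), C, L, B, k);
  const arma::mat Wm(const_cast<double*>(W.begin()), W.nrow(), F, false, true);
  NumericVector Yout(static_cast<R_xlen_t>(F) * L * B);
  arma::mat Ym(Yout.begin(), F, static_cast<arma::uword>(L) * B, false, true);
  Ym = Wm.t() * cols;
  Ym.each_col() += arma::vec(const_cast<double*>(bias.begin()), F, false, true);
  Yout.attr("dim") = IntegerVector::create(F, L, B);
  return Yout;
}

// [[Rcpp::export]]
List conv1d_bwd(const NumericVector& X, const NumericMatrix& W,
                const NumericVector& dY, int k) {
  IntegerVector d = X.attr("dim");
  const int C = d[0], L = d[1], B = d[2], P = (k - 1) / 2;
  const int F = W.ncol();
  const int Lp = L + 2 * P;
  arma::mat Xp = pad_tensor(X, C, L, B, P);
  arma::mat cols(static_cast<arma::uword>(k) * C,
                 static_cast<arma::uword>(L) * B);
  im2col(Xp.memptr(), cols.memptr(), C, L, B, k);
  const arma::mat Wm(const_cast<double*>(W.begin()), W.nrow(), F, false, true);
  const arma::mat dYm(const_cast<double*>(dY.begin()), F,
                      static_cast<arma::uword>(L) * B, false, true);
  arma::mat dW = cols * dYm.t();
  arma::vec db = arma::sum(dYm, 1);
  arma::mat dcols = Wm * dYm;
  // col2im scatter-add back into the padded tensor, then strip the padding
  arma::mat dXp(static_cast<arma::uword>(C) * Lp, B, arma::fill::zeros);
  const std::size_t kc = static_cast<std::size_t>(k) * C;
  std::size_t col = 0;
  for (int b = 0; b < B; ++b) {
    double* base = dXp.colptr(b);
    for (int t = 0; t < L; ++t, ++col) {
      const double* src = dcols.colptr(col);
      double* dst = base + static_cast<std::size_t>(t) * C;
      for (std::size_t i = 0; i < kc; ++i) dst[i] += src[i];
    }
  }
  NumericVector dX(static_cast<R_xlen_t>(C) * L * B);
  for (int b = 0; b < B; ++b)
    std::copy(dXp.colptr(b) + static_cast<std::size_t>(P) * C,
              dXp.colptr(b) + static_cast<std::size_t>(P) * C +
                static_cast<std::size_t>(C) * L,
              dX.begin() + static_cast<std::size_t>(b) * C * L);
  dX.attr("dim") = IntegerVector::create(C, L, B);
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dX"] = dX);
}

// out-of-place ReLU with mask reuse on the backward pass
// [[Rcpp::export]]
NumericVector relu_fwd(const NumericVector& X) {
  NumericVector Y = clone(X);
  for (double* p = Y.begin(); p != Y.end(); ++p)
    if (*p < 0) *p = 0;
  Y.attr("dim") = X.attr("dim");
  return Y;
}

// [[Rcpp::export]]
NumericVector relu_bwd(const NumericVector& X, const NumericVector& dY) {
  NumericVector dX = clone(dY);
  const double* x = X.begin();
  double* p = dX.begin();
  for (R_xlen_t i = 0; i < dX.size(); ++i)
    if (x[i] <= 0) p[i] = 0;
  dX.attr("dim") = dY.attr("dim");
  return dX;
}

// fused inference-mode batchnorm: y = a[c] * x + b[c], channels-first
// [[Rcpp::export]]
NumericVector bn_affine(const NumericVector& X, const NumericVector& a,
                        const NumericVector& b) {
  const int C = a.size();
  NumericVector Y(X.size());
  const double* x = X.begin();
  double* y = Y.begin();
  const double* ap = a.begin();
  const double* bp = b.begin();
  for (R_xlen_t i = 0; i < X.size(); ++i) {
    const int c = static_cast<int>(i % C);
    y[i] = ap[c] * x[i] + bp[c];
  }
  Y.attr("dim") = X.attr("dim");
  return Y;
}

// inverted-dropout sampling in one pass (uses the R RNG, so results are
// reproducible under set.seed); returns the dropped tensor, and the mask
// too when keep_mask is true (needed for the backward pass)
// [[Rcpp::export]]
List dropout_fwd(const NumericVector& X, double p, bool keep_mask) {
  const double scale = 1.0 / (1.0 - p);
  NumericVector Y(X.size());
  NumericVector mask(keep_mask ? X.size() : 0);
  const double* x = X.begin();
  double* y = Y.begin();
  double* mk = keep_mask ? mask.begin() : nullptr;
  for (R_xlen_t i = 0; i < X.size(); ++i) {
    const double m = (unif_rand() >= p) ? scale : 0.0;
    y[i] = m * x[i];
    if (keep_mask) mk[i] = m;
  }
  Y.attr("dim") = X.attr("dim");
  return List::create(_["Y"] = Y, _["mask"] = mask);
}

// denoising corruption: zero-masking at rate p plus additive N(0, sd) noise
// [[Rcpp::export]]
NumericVector corrupt_fwd(const NumericVector& X, double p, double sd) {
  NumericVector Y(X.size());
  const double* x = X.begin();
  double* y = Y.begin();
  for (R_xlen_t i = 0; i < X.size(); ++i) {
    double v = (p > 0 && unif_rand() < p) ? 0.0 : x[i];
    if (sd > 0) v += norm_rand() * sd;
    y[i] = v;
  }
  Y.attr("dim") = X.attr("dim");
  return Y;
}

// max/average pooling along L of a (C, L, B) tensor; trailing samples that
// do not fill a pool window are dropped. For max pooling the flat argmax
// index is returned for the backward pass when keep_idx is set.
// [[Rcpp::export]]
List pool_fwd(const NumericVector& X, int s, bool max_pool, bool keep_idx) {
  IntegerVector d = X.attr("dim");
  const int C = d[0], L = d[1], B = d[2];
  const int Lo = L / s;
  NumericVector Y(static_cast<R_xlen_t>(C) * Lo * B);
  IntegerVector idx(keep_idx && max_pool ? Y.size() : 0);
  const double* x = X.begin();
  double* y = Y.begin();
  R_xlen_t o = 0;
  for (int b = 0; b < B; ++b) {
    const double* xb = x + static_cast<R_xlen_t>(b) * C * L;
    for (int t = 0; t < Lo; ++t) {
      for (int c = 0; c < C; ++c, ++o) {
        if (max_pool) {
          double best = xb[(static_cast<R_xlen_t>(t) * s) * C + c];
          R_xlen_t best_j = (static_cast<R_xlen_t>(t) * s) * C + c;
          for (int j = 1; j < s; ++j) {
            const R_xlen_t at = (static_cast<R_xlen_t>(t) * s + j) * C + c;
            if (xb[at] > best) { best = xb[at]; best_j = at; }
          }
          y[o] = best;
          if (keep_idx) idx[o] = static_cast<int>(
            best_j + static_cast<R_xlen_t>(b) * C * L);
        } else {
          double acc = 0;
          for (int j = 0; j < s; ++j)
            acc += xb[(static_cast<R_xlen_t>(t) * s + j) * C + c];
          y[o] = acc / s;
        }
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(C, Lo, B);
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(const NumericVector& dY, const IntegerVector& idx,
                          int C, int L, int B) {
  NumericVector dX(static_cast<R_xlen_t>(C) * L * B);
  const double* dy = dY.begin();
  double* dx = dX.begin();
  for (R_xlen_t o = 0; o < dY.size(); ++o) dx[idx[o]] += dy[o];
  dX.attr("dim") = IntegerVector::create(C, L, B);
  return dX;
}

// nearest-neighbour upsampling along L to an exact target length: each
// source step is repeated s times, trimmed or extended (repeating the last
// step) to tgt
// [[Rcpp::export]]
NumericVector upsample_fwd(const NumericVector& X, int s, int tgt) {
  IntegerVector d = X.attr("dim");
  const int C = d[0], L = d[1], B = d[2];
  NumericVector Y(static_cast<R_xlen_t>(C) * tgt * B);
  const double* x = X.begin();
  double* y = Y.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = x + static_cast<R_xlen_t>(b) * C * L;
    double* yb = y + static_cast<R_xlen_t>(b) * C * tgt;
    for (int t = 0; t < tgt; ++t) {
      int src = t / s;
      if (src >= L) src = L - 1;
      std::copy(xb + static_cast<R_xlen_t>(src) * C,
                xb + static_cast<R_xlen_t>(src + 1) * C,
                yb + static_cast<R_xlen_t>(t) * C);
    }
  }
  Y.attr("dim") = IntegerVector::create(C, tgt, B);
  return Y;
}

// [[Rcpp::export]]
NumericVector upsample_bwd(const NumericVector& dY, int s, int L) {
  IntegerVector d = dY.attr("dim");
  const int C = d[0], tgt = d[1], B = d[2];
  NumericVector dX(static_cast<R_xlen_t>(C) * L * B);
  const double* dy = dY.begin();
  double* dx = dX.begin();
  for (int b = 0; b < B; ++b) {
    const double* dyb = dy + static_cast<R_xlen_t>(b) * C * tgt;
    double* dxb = dx + static_cast<R_xlen_t>(b) * C * L;
    for (int t = 0; t < tgt; ++t) {
      int src = t / s;
      if (src >= L) src = L - 1;
      for (int c = 0; c < C; ++c)
        dxb[static_cast<R_xlen_t>(src) * C + c] +=
          dyb[static_cast<R_xlen_t>(t) * C + c];
    }
  }
  dX.attr("dim") = IntegerVector::create(C, L, B);
  return dX;
}
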