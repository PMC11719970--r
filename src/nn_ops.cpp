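// 1D convolution and pooling primitives (forward + backward) for the
// diagnosis and multi-class networks. Batched arrays use the R layout
// (batch, length, channels); convolution is im2col + GEMM. The weight matrix
// is (k * in_channels) x out_channels with row index j + k*c for kernel
// offset j and input channel c.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

arma::cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d (batch, length, channels) array");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false);
}

NumericVector cube_to_r(const arma::cube& c) {
  NumericVector out(c.begin(), c.end());
  out.attr("dim") = IntegerVector::create(
      static_cast<int>(c.n_rows), static_cast<int>(c.n_cols),
      static_cast<int>(c.n_slices));
  return out;
}

int conv_out_len(int L, int k, int stride, int pad) {
  const int num = L + 2 * pad - k;
  if (num < 0) return 0;
  return num / stride + 1;
}

arma::mat im2col(const arma::cube& X, int k, int stride, int pad, int L_out) {
  const int B = X.n_rows, L = X.n_cols, C = X.n_slices;
  arma::mat M(static_cast<arma::uword>(B) * L_out,
              static_cast<arma::uword>(k) * C, arma::fill::zeros);
  // the batch dimension is contiguous in both X and M, so copy B-blocks
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j) {
      const arma::uword col = j + static_cast<arma::uword>(k) * c;
      double* mcol = M.colptr(col);
      const double* xsl = X.slice_colptr(c, 0);
      for (int lo = 0; lo < L_out; ++lo) {
        const int t = lo * stride + j - pad;
        if (t < 0 || t >= L) continue;
        std::memcpy(mcol + static_cast<size_t>(B) * lo,
                    xsl + static_cast<size_t>(B) * t,
                    sizeof(double) * B);
      }
    }
  return M;
}

} // namespace

// [[Rcpp::export]]
NumericVector conv1d_fwd_cpp(NumericVector Xr, const arma::mat& W,
                             const arma::vec& bias, int k, int stride,
                             int pad) {
  arma::cube X = as_cube(Xr);
  const int B = X.n_rows, L = X.n_cols, C = X.n_slices;
  const int F = static_cast<int>(W.n_cols);
  if (static_cast<int>(W.n_rows) != k * C)
    stop("conv weight shape mismatch: expected %d rows, got %d", k * C,
         static_cast<int>(W.n_rows));
  const int L_out = conv_out_len(L, k, stride, pad);
  if (L_out < 1)
    stop("input length %d too small for kernel %d (stride %d, pad %d)", L, k,
         stride, pad);
  arma::mat M = im2col(X, k, stride, pad, L_out);
  arma::mat Y = M * W;
  Y.each_row() += bias.t();
  arma::cube out(Y.memptr(), B, L_out, F);
  return cube_to_r(out);
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(NumericVector Xr, const arma::mat& W, NumericVector dYr,
                    int k, int stride, int pad) {
  arma::cube X = as_cube(Xr);
  arma::cube dY = as_cube(dYr);
  const int B = X.n_rows, L = X.n_cols, C = X.n_slices;
  const int L_out = dY.n_cols, F = dY.n_slices;
  arma::mat M = im2col(X, k, stride, pad, L_out);
  arma::mat dYm(dY.memptr(), static_cast<arma::uword>(B) * L_out, F, false);
  arma::mat dW = M.t() * dYm;
  arma::vec db = arma::sum(dYm, 0).t();
  arma::mat dM = dYm * W.t();
  arma::cube dX(B, L, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j) {
      const arma::uword col = j + static_cast<arma::uword>(k) * c;
      const double* mcol = dM.colptr(col);
      double* xsl = dX.slice_colptr(c, 0);
      for (int lo = 0; lo < L_out; ++lo) {
        const int t = lo * stride + j - pad;
        if (t < 0 || t >= L) continue;
        double* dst = xsl + static_cast<size_t>(B) * t;
        const double* src = mcol + static_cast<size_t>(B) * lo;
        for (int b = 0; b < B; ++b) dst[b] += src[b];
      }
    }
  return List::create(_["dX"] = cube_to_r(dX), _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List pool1d_fwd_cpp(NumericVector Xr, int size, bool max_pool) {
  arma::cube X = as_cube(Xr);
  const int B = X.n_rows, L = X.n_cols, C = X.n_slices;
  const int L_out = (L - size) / size + 1;
  if (L_out < 1)
    stop("input length %d too small for pool size %d", L, size);
  arma::cube Y(B, L_out, C);
  IntegerVector idx(static_cast<R_xlen_t>(B) * L_out * C);
  for (int c = 0; c < C; ++c)
    for (int lo = 0; lo < L_out; ++lo)
      for (int b = 0; b < B; ++b) {
        const int start = lo * size;
        if (max_pool) {
          int arg = start;
          double best = X(b, start, c);
          for (int j = 1; j < size; ++j)
            if (X(b, start + j, c) > best) { best = X(b, start + j, c); arg = start + j; }
          Y(b, lo, c) = best;
          idx[b + static_cast<R_xlen_t>(B) * (lo + static_cast<R_xlen_t>(L_out) * c)] = arg;
        } else {
          double s = 0.0;
          for (int j = 0; j < size; ++j) s += X(b, start + j, c);
          Y(b, lo, c) = s / size;
        }
      }
  return List::create(_["Y"] = cube_to_r(Y), _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool1d_bwd_cpp(NumericVector dYr, IntegerVector idx,
                             IntegerVector dimX, int size, bool max_pool) {
  arma::cube dY = as_cube(dYr);
  const int B = dimX[0], L = dimX[1], C = dimX[2];
  const int L_out = dY.n_cols;
  arma::cube dX(B, L, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int lo = 0; lo < L_out; ++lo)
      for (int b = 0; b < B; ++b) {
        if (max_pool) {
          const int arg =
              idx[b + static_cast<R_xlen_t>(B) * (lo + static_cast<R_xlen_t>(L_out) * c)];
          dX(b, arg, c) += dY(b, lo, c);
        } else {
          const double g = dY(b, lo, c) / size;
          for (int j = 0; j < size; ++j) dX(b, lo * size + j, c) += g;
        }
      }
  return cube_to_r(dX);
}
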