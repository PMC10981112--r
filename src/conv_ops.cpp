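// Low-level kernels for the small U-Net: full conv forward/backward via an
// im2col layout transposed to (pixels x features), which matches the
// column-major (H, W, C) array layout R uses for feature maps, so no
// transposes are needed on the R side and all scatter/gather loops run with
// unit stride. Also 2x2 max pooling with argmax bookkeeping.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// cols(ho + Ho*wo, ki + k*kj + k*k*c) = x(ho+ki-pad, wo+kj-pad, c), stride 1
static arma::mat im2col_t(const arma::cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  arma::mat cols(Ho * Wo, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * kj + k * k * c;
        double* dst = cols.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + kj - pad;
          if (wi < 0 || wi >= W) continue;
          const double* src = x.slice_colptr(c, wi);
          const int h0 = std::max(0, pad - ki), h1 = std::min(Ho, H + pad - ki);
          for (int ho = h0; ho < h1; ++ho)
            dst[ho + Ho * wo] = src[ho + ki - pad];
        }
      }
  return cols;
}

// adjoint: scatter-add (HoWo x kkC) columns back onto the H x W x C grid
static arma::cube col2im_t(const arma::mat& cols, int H, int W, int C, int k, int pad) {
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * kj + k * k * c;
        const double* src = cols.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + kj - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = x.slice_colptr(c, wi);
          const int h0 = std::max(0, pad - ki), h1 = std::min(Ho, H + pad - ki);
          for (int ho = h0; ho < h1; ++ho)
            dst[ho + ki - pad] += src[ho + Ho * wo];
        }
      }
  return x;
}

// Convolution (stride 1) with optional ReLU. W: (k*k*Cin) x Cout, b: Cout.
// Returns the (H, W, Cout) output and the im2col matrix for backprop.
// [[Rcpp::export]]
List conv_fwd_cpp(const arma::cube& x, const arma::mat& W, const arma::vec& b,
                  int k, int pad, bool relu) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Ho = H + 2 * pad - k + 1, Wo = Wd + 2 * pad - k + 1;
  if ((int)W.n_rows != k * k * (int)x.n_slices) stop("conv_fwd: weight shape mismatch");
  arma::mat cols = im2col_t(x, k, pad);
  arma::mat out = cols * W;
  out.each_row() += b.t();
  if (relu) out.for_each([](double& v) { if (v < 0) v = 0; });
  arma::cube oc(out.memptr(), Ho, Wo, W.n_cols);
  return List::create(_["out"] = oc, _["cols"] = cols);
}

// Backward pass. dout/out: (H, W, Cout) cubes (out is the post-ReLU forward
// output, used as the ReLU mask); cols: saved im2col matrix.
// [[Rcpp::export]]
List conv_bwd_cpp(const arma::cube& dout, const arma::cube& out,
                  const arma::mat& cols, const arma::mat& W,
                  int Hin, int Win, int Cin, int k, int pad, bool relu) {
  const int n = dout.n_rows * dout.n_cols;
  arma::mat dmat(const_cast<double*>(dout.memptr()), n, dout.n_slices, true);
  if (relu) {
    const double* o = out.memptr();
    double* d = dmat.memptr();
    const int total = n * dout.n_slices;
    for (int i = 0; i < total; ++i) if (o[i] <= 0) d[i] = 0;
  }
  arma::mat dW = cols.t() * dmat;
  arma::vec db = arma::sum(dmat, 0).t();
  arma::mat dcols = dmat * W.t();
  arma::cube dx = col2im_t(dcols, Hin, Win, Cin, k, pad);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// 2x2 max pooling, stride 2, with 1-based argmax indices for backprop.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool2: odd spatial size");
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  int q = 0;
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int hi = 2 * ho + di, wi = 2 * wo + dj;
            const double v = x(hi, wi, c);
            if (v > best) { best = v; bi = hi + H * wi + H * W * c; }
          }
        out(ho, wo, c) = best;
        idx[q++] = bi + 1;
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd_cpp(const arma::cube& dout, const IntegerVector& idx,
                            int H, int W, int C) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  const double* d = dout.memptr();
  const int n = dout.n_elem;
  if (idx.size() != n) stop("maxpool2_bwd: index size mismatch");
  double* p = dx.memptr();
  for (int q = 0; q < n; ++q) p[idx[q] - 1] += d[q];
  return dx;
}
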