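// Hot numeric kernels for the CNN engine: valid stride-1 convolution and
// strided max-pooling, forward and backward, via im2col + one batched BLAS
// GEMM per layer. Batches are (len_in x N) matrices of flattened (H, W, C)
// column-major maps; index matrices are precomputed in R (1-based).
//
// Activation and gradient matrices are written into caller-supplied buffers
// that the R side reuses across minibatches, and the im2col scratch space is
// grow-only: these matrices run to hundreds of MB for spectrogram batches and
// repeated fresh allocation would dominate the runtime.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
using namespace Rcpp;

static std::vector<double>& scratch(int which, std::size_t n) {
  static std::vector<double> bufs[3];
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which];
}

// gather im2col patches for the whole batch into P: (kk x np*N), sample-major
static void gather_patches(arma::mat& P, const arma::mat& x,
                           const IntegerMatrix& idx) {
  const arma::uword N = x.n_cols;
  const arma::uword kk = idx.nrow(), np = idx.ncol();
  const int* ip = idx.begin();
  for (arma::uword n = 0; n < N; ++n) {
    const double* xc = x.colptr(n);
    double* Pp = P.colptr(n * np);
    for (arma::uword e = 0; e < kk * np; ++e) Pp[e] = xc[ip[e] - 1];
  }
}

// x: (len_in x N); idx: (kk x np); K: (kk x c_out); b: c_out.
// Writes ((np * c_out) x N) into `outR`; per sample the layout is
// position-fastest, channel next, i.e. the flattened (H2, W2, c_out)
// column-major map. An immediately following ReLU can be fused in.
// [[Rcpp::export]]
void conv_forward_cpp(const arma::mat& x, const IntegerMatrix& idx,
                      const arma::mat& K, const arma::vec& b,
                      const bool relu, NumericMatrix outR) {
  const arma::uword N = x.n_cols;
  const arma::uword kk = idx.nrow(), np = idx.ncol();
  const arma::uword c_out = K.n_cols;
  if ((arma::uword)outR.nrow() != np * c_out || (arma::uword)outR.ncol() != N)
    stop("conv_forward_cpp: output buffer has wrong shape");
  arma::mat P(scratch(0, kk * np * N).data(), kk, np * N, false, true);
  gather_patches(P, x, idx);
  arma::mat O(scratch(1, np * N * c_out).data(), np * N, c_out, false, true);
  O = P.t() * K;                               // dgemm, transpose folded in
  for (arma::uword n = 0; n < N; ++n) {
    double* oc = outR.begin() + n * np * c_out;
    for (arma::uword c = 0; c < c_out; ++c) {
      const double* src = O.colptr(c) + n * np;
      const double bc = b[c];
      double* dst = oc + c * np;
      if (relu) {
        for (arma::uword j = 0; j < np; ++j) {
          double v = src[j] + bc;
          dst[j] = v > 0 ? v : 0;
        }
      } else {
        for (arma::uword j = 0; j < np; ++j) dst[j] = src[j] + bc;
      }
    }
  }
}

// dout: ((np * c_out) x N) gradient w.r.t. the conv output (post-activation
// when `relu` was fused; `out` is then that output and supplies the ReLU
// derivative). Returns list(W, b); the input gradient is written into `dxR`
// unless `need_dx` is false (first layer, gradient unused).
// [[Rcpp::export]]
List conv_backward_cpp(const arma::mat& x, const IntegerMatrix& idx,
                       const arma::mat& K, const arma::mat& dout,
                       const arma::mat& out, const bool relu,
                       const bool need_dx, NumericMatrix dxR) {
  const arma::uword N = x.n_cols;
  const arma::uword kk = idx.nrow(), np = idx.ncol();
  const arma::uword c_out = K.n_cols;
  const arma::uword len_in = x.n_rows;
  arma::mat P(scratch(0, kk * np * N).data(), kk, np * N, false, true);
  gather_patches(P, x, idx);
  // restack dout into (np*N x c_out), rows sample-major, matching P's columns
  arma::mat D(scratch(1, np * N * c_out).data(), np * N, c_out, false, true);
  for (arma::uword n = 0; n < N; ++n) {
    const double* dc = dout.colptr(n);
    const double* oc = relu ? out.colptr(n) : nullptr;
    for (arma::uword c = 0; c < c_out; ++c) {
      double* dst = D.colptr(c) + n * np;
      const double* sp = dc + c * np;
      if (relu) {
        const double* op = oc + c * np;
        for (arma::uword j = 0; j < np; ++j) dst[j] = op[j] > 0 ? sp[j] : 0;
      } else {
        std::memcpy(dst, sp, sizeof(double) * np);
      }
    }
  }
  arma::mat dW = P * D;                        // (kk x c_out)
  arma::vec db = arma::sum(D, 0).t();
  if (need_dx) {
    if ((arma::uword)dxR.nrow() != len_in || (arma::uword)dxR.ncol() != N)
      stop("conv_backward_cpp: gradient buffer has wrong shape");
    arma::mat DP(scratch(2, np * N * kk).data(), np * N, kk, false, true);
    DP = D * K.t();                            // (np*N x kk)
    std::fill(dxR.begin(), dxR.end(), 0.0);
    const int* ip = idx.begin();
    for (arma::uword n = 0; n < N; ++n) {
      double* dxc = dxR.begin() + n * len_in;
      for (arma::uword r = 0; r < kk; ++r) {
        const double* dpc = DP.colptr(r) + n * np;
        const int* ir = ip + r;
        for (arma::uword j = 0; j < np; ++j) dxc[ir[j * kk] - 1] += dpc[j];
      }
    }
  }
  return List::create(Named("W") = dW, Named("b") = db);
}

// idx: (pp x np) pooling-window gather indices. Writes pooled values into
// `outR` and the 1-based input position of each maximum (first maximum on
// ties) into `srcR`.
// [[Rcpp::export]]
void pool_forward_cpp(const arma::mat& x, const IntegerMatrix& idx,
                      NumericMatrix outR, IntegerMatrix srcR) {
  const arma::uword N = x.n_cols;
  const arma::uword pp = idx.nrow(), np = idx.ncol();
  if ((arma::uword)outR.nrow() != np || (arma::uword)outR.ncol() != N)
    stop("pool_forward_cpp: output buffer has wrong shape");
  const int* ip = idx.begin();
  for (arma::uword n = 0; n < N; ++n) {
    const double* xc = x.colptr(n);
    double* oc = outR.begin() + n * np;
    int* sc = srcR.begin() + n * np;
    for (arma::uword j = 0; j < np; ++j) {
      const int* w = ip + j * pp;
      double best = xc[w[0] - 1];
      int besti = w[0];
      for (arma::uword r = 1; r < pp; ++r) {
        double v = xc[w[r] - 1];
        if (v > best) { best = v; besti = w[r]; }
      }
      oc[j] = best;
      sc[j] = besti;
    }
  }
}

// [[Rcpp::export]]
void pool_backward_cpp(const IntegerMatrix& src, const arma::mat& dout,
                       NumericMatrix dxR) {
  const arma::uword np = src.nrow(), N = src.ncol();
  const arma::uword len_in = dxR.nrow();
  std::fill(dxR.begin(), dxR.end(), 0.0);
  const int* sp = src.begin();
  for (arma::uword n = 0; n < N; ++n) {
    double* dxc = dxR.begin() + n * len_in;
    const double* dc = dout.colptr(n);
    const int* sc = sp + n * np;
    for (arma::uword j = 0; j < np; ++j) dxc[sc[j] - 1] += dc[j];
  }
}
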