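// Hot kernels of the network engine: the spectral ('same'-padded 1-d)
// convolution and the SGD-momentum update. Shapes follow the R side: a
// mini-batch is a [filters x (L*B)] matrix of side-by-side sample blocks.
// The convolution unrolls its taps (im2col) so each pass is one large GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat pad_blocks(const arma::mat& x, int L, int B, int LP,
                            int offset) {
  arma::mat xpad(x.n_rows, (arma::uword)LP * B, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    xpad.cols((arma::uword)s * LP + offset,
              (arma::uword)s * LP + offset + L - 1) =
      x.cols((arma::uword)s * L, (arma::uword)s * L + L - 1);
  return xpad;
}

// gather tap windows: out block-row j <- xpad columns shifted by tap(j)
static arma::mat unroll_taps(const arma::mat& xpad, int L, int B, int LP,
                             int K, bool reversed) {
  const int f = xpad.n_rows;
  arma::mat xc((arma::uword)f * K, (arma::uword)L * B);
  for (int j = 0; j < K; ++j) {
    const int tap = reversed ? (K - 1 - j) : j;
    for (int s = 0; s < B; ++s)
      xc.submat((arma::uword)j * f, (arma::uword)s * L,
                (arma::uword)(j + 1) * f - 1, (arma::uword)s * L + L - 1) =
        xpad.cols((arma::uword)s * LP + tap,
                  (arma::uword)s * LP + tap + L - 1);
  }
  return xc;
}

// [[Rcpp::export(name = ".conv2_fwd_cpp")]]
List conv2_fwd_cpp(const arma::cube& W, const arma::vec& b,
                   const arma::mat& x, int L, int B) {
  const int K = W.n_slices;
  const int fout = W.n_rows, fin = W.n_cols;
  const int pad_left = (K - 1) / 2;
  const int LP = L + K - 1;

  arma::mat xpad = pad_blocks(x, L, B, LP, pad_left);
  arma::mat xc = unroll_taps(xpad, L, B, LP, K, false);
  // W flattened as [fout x fin*K] matches the cube's memory layout
  const arma::mat Wmat(const_cast<double*>(W.memptr()), fout,
                       (arma::uword)fin * K, false, true);
  arma::mat y = Wmat * xc;
  y.each_col() += b;
  return List::create(_["y"] = y, _["xc"] = xc);
}

// [[Rcpp::export(name = ".conv2_bwd_cpp")]]
List conv2_bwd_cpp(const arma::cube& W, const arma::mat& dy,
                   const arma::mat& xc, int L, int B) {
  const int K = W.n_slices;
  const int fout = W.n_rows, fin = W.n_cols;
  const int pad_left = (K - 1) / 2;
  const int LP = L + K - 1;

  arma::mat dWmat = dy * xc.t();                  // [fout x fin*K]
  arma::cube dW(dWmat.memptr(), fout, fin, K);    // same memory layout
  arma::vec db = arma::sum(dy, 1);

  // dx as correlation with the reversed kernel over padded dy: placing dy
  // at offset K-1-pad_left makes reversed tap j line up with the shift the
  // chain rule requires
  arma::mat dypad = pad_blocks(dy, L, B, LP, K - 1 - pad_left);
  arma::mat dyc = unroll_taps(dypad, L, B, LP, K, true);
  arma::mat Wrev(fin, (arma::uword)fout * K);
  for (int j = 0; j < K; ++j)
    Wrev.cols((arma::uword)j * fout, (arma::uword)(j + 1) * fout - 1) =
      W.slice(j).t();
  arma::mat dx = Wrev * dyc;
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// in-place SGD with momentum: v <- mom*v - lr*g - 2*decay*lr*p; p <- p + v.
// p and v must be uniquely-owned buffers (the training loop deep-copies the
// parameter tree once at entry).
// [[Rcpp::export(name = ".sgd_step_cpp")]]
void sgd_step_cpp(NumericVector p, const NumericVector g, NumericVector v,
                  double lr, double momentum, double decay) {
  const R_xlen_t n = p.size();
  if (g.size() != n || v.size() != n) stop("sgd step: length mismatch");
  double* pp = REAL(p);
  const double* pg = REAL(g);
  double* pv = REAL(v);
  const double c = 2.0 * decay * lr;
  for (R_xlen_t i = 0; i < n; ++i) {
    pv[i] = momentum * pv[i] - lr * pg[i] - c * pp[i];
    pp[i] += pv[i];
  }
}
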