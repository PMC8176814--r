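// 2-D convolution primitives for the reconstruction networks.
// Layout: images are H x W x C cubes; a conv weight is a (Cout x Cin*k*k)
// matrix so both passes reduce to one BLAS gemm via im2col/col2im.
// Padding is zero ("same" output size), stride 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int r = k / 2;
  mat cols(C * k * k, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int dj = -r; dj <= r; ++dj) {
      for (int di = -r; di <= r; ++di) {
        const int row = c * k * k + (dj + r) * k + (di + r);
        // source pixel (i+di, j+dj) -> column j*H+i
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = xs.colptr(j + dj) + (i0 + di);
          double* dst = cols.colptr(j * H + i0) + row;
          for (int i = i0; i < i1; ++i, dst += cols.n_rows)
            *dst = src[i - i0];
        }
      }
    }
  }
  return cols;
}

// scatter-add the column matrix back into an image cube (adjoint of im2col)
static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k) {
  const int r = k / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xs = x.slice(c);
    for (int dj = -r; dj <= r; ++dj) {
      for (int di = -r; di <= r; ++di) {
        const int row = c * k * k + (dj + r) * k + (di + r);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          double* dst = xs.colptr(j + dj) + (i0 + di);
          const double* src = cols.colptr(j * H + i0) + row;
          for (int i = i0; i < i1; ++i, src += cols.n_rows)
            dst[i - i0] += *src;
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  mat cols = im2col(x, k);            // (Cin*k*k) x (H*W)
  mat y = w * cols;                   // Cout x (H*W)
  y.each_col() += b;
  cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.row(c).t(), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& dy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  mat dym(Cout, H * W);
  for (int c = 0; c < Cout; ++c)
    dym.row(c) = vectorise(dy.slice(c)).t();
  mat cols = im2col(x, k);
  mat gw = dym * cols.t();            // Cout x (Cin*k*k)
  vec gb = sum(dym, 1);
  mat dcols = w.t() * dym;            // (Cin*k*k) x (H*W)
  cube dx = col2im(dcols, H, W, Cin, k);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
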