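// Compiled kernels for the convolution and batch-norm layers.
//
// Tensors are (B*H*W) x C matrices, image-major and column-major within
// each image.  A same-padded 3x3 convolution with weights W_k (Cin x Cout,
// one per stencil offset k) is evaluated as
//     out = sum_k shift_k(x * W_k)
// i.e. one gemm into an N x 9Cout buffer followed by a shift-accumulate,
// exploiting that a pure shift commutes with the per-pixel linear map.
// The backward pass is the exact adjoint: the opposite shifts gather dY
// into an N x 9Cout buffer, after which dW and dX are single gemms.  This
// avoids materializing (and caching between passes) an im2col matrix; the
// only stored activation is the layer input itself.  Weights are stored as
// a Cin x 9Cout matrix, column block k = W_k, with k ordered dy fastest
// (dy, dx in {-1,0,1}^2).  Large outputs are written straight into
// R-allocated matrices (arma views) to avoid copy-on-return.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// out(:,c) += T(:, k*Cout+c) shifted by (dy, dx): out(y,x) += T(y+dy, x+dx)
static void shift_accumulate(const mat& T, mat& out, int H, int W, int B,
                             int Cout) {
  const int HW = H * W;
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++k) {
      const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
      if (y1 <= y0) continue;
      for (int c = 0; c < Cout; ++c) {
        const double* src = T.colptr(k * Cout + c);
        double* dst = out.colptr(c);
        for (int b = 0; b < B; ++b) {
          const int off = b * HW;
          for (int xx = 0; xx < W; ++xx) {
            const int xs = xx + dx;
            if (xs < 0 || xs >= W) continue;
            double* d = dst + off + xx * H + y0;
            const double* s = src + off + xs * H + y0 + dy;
            for (int y = 0; y < y1 - y0; ++y) d[y] += s[y];
          }
        }
      }
    }
  }
}

// S(:, k*C+c) = dy-matrix column c shifted by the OPPOSITE offset of k
static void shift_gather(const mat& dY, mat& S, int H, int W, int B, int C) {
  const int HW = H * W;
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++k) {
      const int ody = -dy, odx = -dx;
      const int y0 = std::max(0, -ody), y1 = std::min(H, H - ody);
      if (y1 <= y0) continue;
      for (int c = 0; c < C; ++c) {
        const double* src = dY.colptr(c);
        double* dst = S.colptr(k * C + c);
        for (int b = 0; b < B; ++b) {
          const int off = b * HW;
          for (int xx = 0; xx < W; ++xx) {
            const int xs = xx + odx;
            if (xs < 0 || xs >= W) continue;
            std::memcpy(dst + off + xx * H + y0,
                        src + off + xs * H + y0 + ody,
                        (y1 - y0) * sizeof(double));
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericMatrix conv3_fwd_cpp(const arma::mat& x, const arma::mat& W,
                                  const arma::vec& bias, int H, int Wd,
                                  int B) {
  const int N = x.n_rows, Cout = W.n_cols / 9;
  mat T = x * W;  // N x 9Cout
  Rcpp::NumericMatrix outR(N, Cout);
  mat out(outR.begin(), N, Cout, false, true);
  out.each_row() = bias.t();
  shift_accumulate(T, out, H, Wd, B, Cout);
  return outR;
}

// [[Rcpp::export]]
Rcpp::List conv3_bwd_cpp(const arma::mat& x, const arma::mat& dy,
                         const arma::mat& W, int H, int Wd, int B) {
  const int N = dy.n_rows, Cout = dy.n_cols, Cin = x.n_cols;
  mat S(N, 9 * Cout, fill::zeros);
  shift_gather(dy, S, H, Wd, B, Cout);
  mat dW = x.t() * S;             // Cin x 9Cout
  vec db = sum(dy, 0).t();
  mat Wt(9 * Cout, Cin);          // rows block k = W_k^T
  for (int k = 0; k < 9; ++k)
    Wt.rows(k * Cout, (k + 1) * Cout - 1) =
      W.cols(k * Cout, (k + 1) * Cout - 1).t();
  Rcpp::NumericMatrix dxR(N, Cin);
  mat dx(dxR.begin(), N, Cin, false, true);
  dx = S * Wt;
  return Rcpp::List::create(Rcpp::Named("dx") = dxR,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List bn_fwd_cpp(const arma::mat& x, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& run_mean,
                      const arma::vec& run_var, bool training,
                      double eps, double momentum) {
  const int N = x.n_rows, C = x.n_cols;
  rowvec mu, v;
  if (training) {
    mu = mean(x, 0);
    v = mean(square(x.each_row() - mu), 0);
  } else {
    mu = run_mean.t();
    v = run_var.t();
  }
  rowvec istd = 1.0 / sqrt(v + eps);
  Rcpp::NumericMatrix xhatR(N, C), outR(N, C);
  mat xhat(xhatR.begin(), N, C, false, true);
  mat out(outR.begin(), N, C, false, true);
  xhat = x.each_row() - mu;
  xhat.each_row() %= istd;
  out = xhat;
  out.each_row() %= gamma.t();
  out.each_row() += beta.t();
  vec new_mean = run_mean, new_var = run_var;
  if (training) {
    new_mean = (1 - momentum) * run_mean + momentum * mu.t();
    new_var = (1 - momentum) * run_var + momentum * v.t();
  }
  return Rcpp::List::create(Rcpp::Named("out") = outR,
                            Rcpp::Named("xhat") = xhatR,
                            Rcpp::Named("istd") = istd.t(),
                            Rcpp::Named("mean") = new_mean,
                            Rcpp::Named("var") = new_var);
}

// [[Rcpp::export]]
Rcpp::List bn_bwd_cpp(const arma::mat& dy, const arma::vec& gamma,
                      const arma::mat& xhat, const arma::vec& istd) {
  const int N = dy.n_rows, C = dy.n_cols;
  vec dgamma = sum(dy % xhat, 0).t();
  vec dbeta = sum(dy, 0).t();
  Rcpp::NumericMatrix dxR(N, C);
  mat dx(dxR.begin(), N, C, false, true);
  dx = dy;
  dx.each_row() %= gamma.t();
  rowvec m1 = mean(dx, 0);
  rowvec m2 = mean(dx % xhat, 0);
  dx.each_row() -= m1;
  dx -= xhat.each_row() % m2;
  dx.each_row() %= istd.t();
  return Rcpp::List::create(Rcpp::Named("dx") = dxR,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// [[Rcpp::export]]
Rcpp::List bn_relu_fwd_cpp(const arma::mat& x, const arma::vec& gamma,
                           const arma::vec& beta, const arma::vec& run_mean,
                           const arma::vec& run_var, bool training,
                           double eps, double momentum) {
  const int N = x.n_rows, C = x.n_cols;
  rowvec mu, v;
  if (training) {
    mu = mean(x, 0);
    v = mean(square(x.each_row() - mu), 0);
  } else {
    mu = run_mean.t();
    v = run_var.t();
  }
  rowvec istd = 1.0 / sqrt(v + eps);
  Rcpp::NumericMatrix xhatR(N, C), outR(N, C);
  mat xhat(xhatR.begin(), N, C, false, true);
  mat out(outR.begin(), N, C, false, true);
  xhat = x.each_row() - mu;
  xhat.each_row() %= istd;
  out = xhat;
  out.each_row() %= gamma.t();
  out.each_row() += beta.t();
  out.transform([](double u) { return u > 0 ? u : 0.0; });
  vec new_mean = run_mean, new_var = run_var;
  if (training) {
    new_mean = (1 - momentum) * run_mean + momentum * mu.t();
    new_var = (1 - momentum) * run_var + momentum * v.t();
  }
  return Rcpp::List::create(Rcpp::Named("out") = outR,
                            Rcpp::Named("xhat") = xhatR,
                            Rcpp::Named("istd") = istd.t(),
                            Rcpp::Named("mean") = new_mean,
                            Rcpp::Named("var") = new_var);
}

// [[Rcpp::export]]
Rcpp::List bn_relu_bwd_cpp(const arma::mat& dy, const arma::mat& out,
                           const arma::vec& gamma, const arma::mat& xhat,
                           const arma::vec& istd) {
  const int N = dy.n_rows, C = dy.n_cols;
  mat dz = dy % (out > 0);  // ReLU gate
  vec dgamma = sum(dz % xhat, 0).t();
  vec dbeta = sum(dz, 0).t();
  Rcpp::NumericMatrix dxR(N, C);
  mat dx(dxR.begin(), N, C, false, true);
  dx = dz;
  dx.each_row() %= gamma.t();
  rowvec m1 = mean(dx, 0);
  rowvec m2 = mean(dx % xhat, 0);
  dx.each_row() -= m1;
  dx -= xhat.each_row() % m2;
  dx.each_row() %= istd.t();
  return Rcpp::List::create(Rcpp::Named("dx") = dxR,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// [[Rcpp::export]]
Rcpp::List pool_fwd_cpp(const arma::mat& x, int H, int W, int B) {
  const int C = x.n_cols, Ho = H / 2, Wo = W / 2, HWo = Ho * Wo;
  const int No = HWo * B, HW = H * W;
  Rcpp::NumericMatrix outR(No, C);
  Rcpp::IntegerMatrix argR(No, C);
  mat out(outR.begin(), No, C, false, true);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = out.colptr(c);
    int* arg = &argR(0, c);
    for (int b = 0; b < B; ++b) {
      const int offi = b * HW, offo = b * HWo;
      for (int xo = 0; xo < Wo; ++xo) {
        for (int yo = 0; yo < Ho; ++yo) {
          const int i00 = offi + 2 * xo * H + 2 * yo;
          double best = src[i00];
          int a = 0;
          if (src[i00 + 1] > best) { best = src[i00 + 1]; a = 1; }
          if (src[i00 + H] > best) { best = src[i00 + H]; a = 2; }
          if (src[i00 + H + 1] > best) { best = src[i00 + H + 1]; a = 3; }
          dst[offo + xo * Ho + yo] = best;
          arg[offo + xo * Ho + yo] = a;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = outR,
                            Rcpp::Named("arg") = argR);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix pool_bwd_cpp(const arma::mat& dy,
                                 const Rcpp::IntegerMatrix& arg,
                                 int H, int W, int B) {
  const int C = dy.n_cols, Ho = H / 2, Wo = W / 2, HWo = Ho * Wo, HW = H * W;
  Rcpp::NumericMatrix dxR(HW * B, C);
  for (int c = 0; c < C; ++c) {
    const double* g = dy.colptr(c);
    const int* a = &arg(0, c);
    double* dst = REAL(SEXP(dxR)) + (R_xlen_t)c * HW * B;
    for (int b = 0; b < B; ++b) {
      const int offi = b * HW, offo = b * HWo;
      for (int xo = 0; xo < Wo; ++xo) {
        for (int yo = 0; yo < Ho; ++yo) {
          const int o = offo + xo * Ho + yo;
          const int aa = a[o];
          const int i00 = offi + 2 * xo * H + 2 * yo;
          dst[i00 + (aa == 1 ? 1 : 0) + (aa == 2 ? H : 0) +
              (aa == 3 ? H + 1 : 0)] = g[o];
        }
      }
    }
  }
  return dxR;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix up_fwd_cpp(const arma::mat& x, int H, int W, int B) {
  const int C = x.n_cols, Ho = 2 * H, Wo = 2 * W, HW = H * W, HWo = Ho * Wo;
  Rcpp::NumericMatrix outR(HWo * B, C);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = REAL(SEXP(outR)) + (R_xlen_t)c * HWo * B;
    for (int b = 0; b < B; ++b) {
      const int offi = b * HW, offo = b * HWo;
      for (int xo = 0; xo < Wo; ++xo) {
        const double* s = src + offi + (xo / 2) * H;
        double* d = dst + offo + xo * Ho;
        for (int yo = 0; yo < Ho; ++yo) d[yo] = s[yo / 2];
      }
    }
  }
  return outR;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix up_bwd_cpp(const arma::mat& dy, int H, int W, int B) {
  // adjoint of nearest-neighbour 2x upsampling from (H, W): sum each 2x2
  const int C = dy.n_cols, Ho = 2 * H, HW = H * W, HWo = 4 * HW;
  Rcpp::NumericMatrix dxR(HW * B, C);
  for (int c = 0; c < C; ++c) {
    const double* g = dy.colptr(c);
    double* dst = REAL(SEXP(dxR)) + (R_xlen_t)c * HW * B;
    for (int b = 0; b < B; ++b) {
      const int offo = b * HWo, offi = b * HW;
      for (int x = 0; x < W; ++x) {
        const double* s0 = g + offo + (2 * x) * Ho;
        const double* s1 = g + offo + (2 * x + 1) * Ho;
        double* d = dst + offi + x * H;
        for (int y = 0; y < H; ++y)
          d[y] = s0[2 * y] + s0[2 * y + 1] + s1[2 * y] + s1[2 * y + 1];
      }
    }
  }
  return dxR;
}
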