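#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Layout conventions
// ------------------
// Activations: R arrays with dim (H, W, C, N), column-major (R native).
// Conv weights: matrix of dim (k*k*Cin, F); row index = kr + k*kc + k*k*ci
//   (kernel row fastest, then kernel col, then input channel), matching the
//   im2col row order below. Stride is 1; `pad` zero-pads both axes.

static inline arma::mat im2col_one(const double* x, int H, int W, int C,
                                   int k, int pad, int Ho, int Wo) {
  arma::mat col(k * k * C, (arma::uword)Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* dst = col.colptr((arma::uword)wo * Ho + ho);
      for (int ci = 0; ci < C; ++ci) {
        for (int kc = 0; kc < k; ++kc) {
          int cc = wo - pad + kc;
          for (int kr = 0; kr < k; ++kr) {
            int rr = ho - pad + kr;
            double v = 0.0;
            if (rr >= 0 && rr < H && cc >= 0 && cc < W)
              v = x[rr + (size_t)H * (cc + (size_t)W * ci)];
            dst[kr + k * kc + k * k * ci] = v;
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv_fwd(const NumericVector& x, const NumericMatrix& w,
                           const NumericVector& b, int k, int pad) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 4) stop("x must have dim (H, W, C, N)");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int F = w.ncol();
  if (w.nrow() != k * k * C) stop("weight rows must equal k*k*Cin");
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  if (Ho < 1 || Wo < 1) stop("input smaller than kernel");

  NumericVector out((size_t)Ho * Wo * F * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  const arma::mat wm(const_cast<double*>(w.begin()), w.nrow(), F, false, true);
  const arma::vec bv(const_cast<double*>(b.begin()), F, false, true);

  for (int n = 0; n < N; ++n) {
    const double* xi = x.begin() + (size_t)H * W * C * n;
    arma::mat col = im2col_one(xi, H, W, C, k, pad, Ho, Wo);
    arma::mat o = wm.t() * col;            // F x (Ho*Wo)
    o.each_col() += bv;
    double* dst = out.begin() + (size_t)Ho * Wo * F * n;
    // o(f, wo*Ho + ho) -> dst[ho + Ho*(wo + Wo*f)]
    for (int f = 0; f < F; ++f)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dst[ho + (size_t)Ho * (wo + (size_t)Wo * f)] =
            o(f, (arma::uword)wo * Ho + ho);
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List cpp_conv_bwd(const NumericVector& x, const NumericMatrix& w,
                  const NumericVector& dout, int k, int pad) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int F = w.ncol();
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dW(w.nrow(), F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  const arma::mat wm(const_cast<double*>(w.begin()), w.nrow(), F, false, true);

  arma::mat dout_i(F, (arma::uword)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xi = x.begin() + (size_t)H * W * C * n;
    const double* di = dout.begin() + (size_t)Ho * Wo * F * n;
    for (int f = 0; f < F; ++f)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dout_i(f, (arma::uword)wo * Ho + ho) =
            di[ho + (size_t)Ho * (wo + (size_t)Wo * f)];

    arma::mat col = im2col_one(xi, H, W, C, k, pad, Ho, Wo);
    dW += col * dout_i.t();
    db += arma::sum(dout_i, 1);
    arma::mat dcol = wm * dout_i;          // (k*k*C) x (Ho*Wo)

    double* dxi = dx.begin() + (size_t)H * W * C * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double* src = dcol.colptr((arma::uword)wo * Ho + ho);
        for (int ci = 0; ci < C; ++ci) {
          for (int kc = 0; kc < k; ++kc) {
            int cc = wo - pad + kc;
            if (cc < 0 || cc >= W) continue;
            for (int kr = 0; kr < k; ++kr) {
              int rr = ho - pad + kr;
              if (rr < 0 || rr >= H) continue;
              dxi[rr + (size_t)H * (cc + (size_t)W * ci)] +=
                src[kr + k * kc + k * k * ci];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = wrap(db));
}

// Non-overlapping max pooling, window = stride = size; trailing rows/cols
// that do not fill a window are dropped (floor semantics).
// [[Rcpp::export(rng = false)]]
List cpp_maxpool_fwd(const NumericVector& x, int size) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = H / size, Wo = W / size;
  if (Ho < 1 || Wo < 1) stop("input too small to pool");

  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg((size_t)Ho * Wo * C * N);  // 0-based linear index into x

  for (int n = 0; n < N; ++n) {
    const double* xi = x.begin() + (size_t)H * W * C * n;
    size_t base = (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int dc = 0; dc < size; ++dc) {
            int cc = wo * size + dc;
            for (int dr = 0; dr < size; ++dr) {
              int rr = ho * size + dr;
              size_t idx = rr + (size_t)H * (cc + (size_t)W * c);
              if (xi[idx] > best) { best = xi[idx]; besti = idx; }
            }
          }
          size_t oidx = ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
          out[oidx] = best;
          arg[oidx] = (int)(base + besti);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_maxpool_bwd(const IntegerVector& argmax,
                              const NumericVector& dout,
                              const IntegerVector& xdim) {
  size_t total = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(total);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    dx[argmax[i]] += dout[i];
  return dx;
}
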