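// Low-level neural-network kernels.
//
// Tensor layout follows R's column-major 4D arrays: dim = (H, W, C, N),
// element (h, w, c, n) at offset h + H*(w + W*(c + C*n)), all 0-based here.
// Convolutions are stride-1 "same" with odd kernels; pooling and the
// transposed convolution are the fixed 2x2/stride-2 pair the architecture
// uses. Heavy lifting is im2col + BLAS gemm via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C,
                             int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Build im2col matrix for one sample: rows = H*W output pixels,
// cols = kh*kw*Cin, zero padding outside.
static void im2col(const double* x, int H, int W, int Cin, int kh, int kw,
                   arma::mat& out) {
  const int pad_h = (kh - 1) / 2, pad_w = (kw - 1) / 2;
  out.zeros(H * W, kh * kw * Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * ci);
        for (int w = 0; w < W; ++w) {
          const int ws = w + j - pad_w;
          if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hs = h + i - pad_h;
            if (hs < 0 || hs >= H) continue;
            out(h + H * w, k) = xc[hs + H * ws];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dFwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be (kh, kw, Cin, Cout)");
  const int kh = wd[0], kw = wd[1], wCin = wd[2], Cout = wd[3];
  if (wCin != Cin) stop("input channel mismatch");
  if (kh % 2 == 0 || kw % 2 == 0) stop("kernel size must be odd");

  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  arma::mat Xcol;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, kh, kw, Xcol);
    arma::mat Y = Xcol * Wm;  // (HW x Cout)
    double* yn = y.begin() + (size_t)H * W * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      double* yc = yn + (size_t)H * W * co;
      const double* src = Y.colptr(co);
      for (int p = 0; p < H * W; ++p) yc[p] = src[p] + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2dBwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int pad_h = (kh - 1) / 2, pad_w = (kw - 1) / 2;

  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  arma::mat dWm(kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat Xcol;

  for (int n = 0; n < N; ++n) {
    arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)H * W * Cout * n,
                  H * W, Cout, false);
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, kh, kw, Xcol);
    dWm += Xcol.t() * dYn;
    db += arma::sum(dYn, 0).t();
    arma::mat dXcol = dYn * Wm.t();  // (HW x K)
    double* dxn = dx.begin() + (size_t)H * W * Cin * n;
    for (int ci = 0; ci < Cin; ++ci) {
      double* dxc = dxn + (size_t)H * W * ci;
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          const int k = i + kh * (j + kw * ci);
          const double* col = dXcol.colptr(k);
          for (int wcol = 0; wcol < W; ++wcol) {
            const int ws = wcol + j - pad_w;
            if (ws < 0 || ws >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int hs = h + i - pad_h;
              if (hs < 0 || hs >= H) continue;
              dxc[hs + H * ws] += col[h + H * wcol];
            }
          }
        }
      }
    }
  }
  NumericVector dwOut(dWm.begin(), dWm.end());
  dwOut.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwOut,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool2Fwd")]]
List maxpool2_fwd(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; int bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const double v = xc[(2 * ho + di) + H * (2 * wo + dj)];
              if (v > best) { best = v; bi = di + 2 * dj; }
            }
          // column-major within the (Ho, Wo) plane
          y[o + ho + (size_t)Ho * wo] = best;
          idx[o + ho + (size_t)Ho * wo] = bi;
        }
      o += (size_t)Ho * Wo;
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2Bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector d = dy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const int bi = idx[o + ho + (size_t)Ho * wo];
          const int di = bi % 2, dj = bi / 2;
          dxc[(2 * ho + di) + H * (2 * wo + dj)] += dy[o + ho + (size_t)Ho * wo];
        }
      o += (size_t)Ho * Wo;
    }
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2 (learned upsampling).
// w dims: (2, 2, Cin, Cout); output is (2H, 2W, Cout, N).
// [[Rcpp::export(name = ".convT2Fwd")]]
NumericVector convT2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* yc = y.begin() + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      for (int p = 0; p < Ho * Wo; ++p) yc[p] = b[co];
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = x.begin() + (size_t)H * W * (ci + (size_t)Cin * n);
        const double* wk = w.begin() + 4 * (ci + (size_t)Cin * co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = xc[i + H * j];
            double* base = yc + (2 * i) + Ho * (2 * j);
            base[0] += v * wk[0];          // (di=0, dj=0)
            base[1] += v * wk[1];          // (di=1, dj=0)
            base[Ho] += v * wk[2];         // (di=0, dj=1)
            base[Ho + 1] += v * wk[3];     // (di=1, dj=1)
          }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".convT2Bwd")]]
List convT2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  const int Ho = 2 * H;
  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* dyc =
          dy.begin() + (size_t)Ho * 2 * W * (co + (size_t)Cout * n);
      double acc = 0.0;
      for (size_t p = 0; p < (size_t)Ho * 2 * W; ++p) acc += dyc[p];
      db[co] += acc;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = x.begin() + (size_t)H * W * (ci + (size_t)Cin * n);
        double* dxc = dx.begin() + (size_t)H * W * (ci + (size_t)Cin * n);
        const double* wk = w.begin() + 4 * (ci + (size_t)Cin * co);
        double* dwk = dw.begin() + 4 * (ci + (size_t)Cin * co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double* base = dyc + (2 * i) + Ho * (2 * j);
            const double g00 = base[0], g10 = base[1], g01 = base[Ho],
                         g11 = base[Ho + 1];
            dxc[i + H * j] +=
                g00 * wk[0] + g10 * wk[1] + g01 * wk[2] + g11 * wk[3];
            const double v = xc[i + H * j];
            dwk[0] += v * g00; dwk[1] += v * g10;
            dwk[2] += v * g01; dwk[3] += v * g11;
          }
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
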