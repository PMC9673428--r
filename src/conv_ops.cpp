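// Low-level network primitives on 4-D arrays laid out (H, W, C, N), R
// column-major.  Convolutions are computed as one BLAS gemm per kernel
// offset: the input window shifted by (dy, dx) forms an (Ho*Wo) x Cin
// matrix that multiplies the Cin x Cout weight slab for that offset.
// Dilation enters only through the offset stride, so ordinary (rate 1),
// dilated and zero-upsampled transposed convolutions all share this path.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::uword dim4(const NumericVector& v, int k) {
  IntegerVector d = v.attr("dim");
  return d[k];
}

// y[i,j,co,n] = b[co] + sum_{a,t,ci} x[i + a*rate - pt, j + t*rate - pl, ci, n] * w[a,t,ci,co]
// out-of-range x treated as zero (zero padding).
// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                             int rate, int pt, int pl, int pb, int pr) {
  const arma::uword H = dim4(x, 0), W = dim4(x, 1), Ci = dim4(x, 2), N = dim4(x, 3);
  const arma::uword K = dim4(w, 0), Kw = dim4(w, 1), Co = dim4(w, 3);
  if (dim4(w, 2) != Ci) stop("weight in-channels (%d) do not match input channels (%d)",
                             (int)dim4(w, 2), (int)Ci);
  if (rate < 1) stop("dilation rate must be >= 1");
  const long Ho_l = (long)H + pt + pb - (long)rate * (K - 1);
  const long Wo_l = (long)W + pl + pr - (long)rate * (Kw - 1);
  if (Ho_l < 1 || Wo_l < 1)
    stop("dilated kernel (span %d) exceeds padded input (%d x %d)",
         (int)(rate * (K - 1) + 1), (int)(H + pt + pb), (int)(W + pl + pr));
  const arma::uword Ho = Ho_l, Wo = Wo_l;

  NumericVector y(Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  const double* xp = x.begin();
  double* yp = y.begin();

  arma::mat Xs(Ho * Wo, Ci);
  arma::mat Wab(Ci, Co);
  arma::rowvec brow(bias.begin(), Co);

  for (arma::uword n = 0; n < N; ++n) {
    arma::mat Ym(yp + n * Ho * Wo * Co, Ho * Wo, Co, false, true);
    Ym.each_row() = brow;
    for (arma::uword a = 0; a < K; ++a) {
      const long oy = (long)a * rate - pt;
      const long i0 = std::max(0L, -oy), i1 = std::min((long)Ho, (long)H - oy);
      if (i1 <= i0) continue;
      for (arma::uword t = 0; t < Kw; ++t) {
        const long ox = (long)t * rate - pl;
        const long j0 = std::max(0L, -ox), j1 = std::min((long)Wo, (long)W - ox);
        if (j1 <= j0) continue;
        Xs.zeros();
        for (arma::uword ci = 0; ci < Ci; ++ci) {
          const double* xc = xp + ((n * Ci + ci) * W) * H;
          double* xsc = Xs.colptr(ci);
          for (long j = j0; j < j1; ++j)
            std::memcpy(xsc + j * Ho + i0, xc + (j + ox) * H + (i0 + oy),
                        sizeof(double) * (i1 - i0));
        }
        for (arma::uword ci = 0; ci < Ci; ++ci)
          for (arma::uword co = 0; co < Co; ++co)
            Wab(ci, co) = w[a + t * K + ci * K * Kw + co * K * Kw * Ci];
        Ym += Xs * Wab;
      }
    }
  }
  return y;
}

// Gradients of cpp_conv2d_fwd w.r.t. input, weights and bias.
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int rate, int pt, int pl, int pb, int pr) {
  const arma::uword H = dim4(x, 0), W = dim4(x, 1), Ci = dim4(x, 2), N = dim4(x, 3);
  const arma::uword K = dim4(w, 0), Kw = dim4(w, 1), Co = dim4(w, 3);
  const arma::uword Ho = dim4(gy, 0), Wo = dim4(gy, 1);

  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Co);

  const double* xp = x.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();

  arma::mat Xs(Ho * Wo, Ci), GXs(Ho * Wo, Ci), Wab(Ci, Co), GWab(Ci, Co);
  arma::rowvec gbacc(Co, arma::fill::zeros);

  for (arma::uword n = 0; n < N; ++n) {
    const arma::mat Gm(const_cast<double*>(gyp + n * Ho * Wo * Co), Ho * Wo, Co, false, true);
    gbacc += arma::sum(Gm, 0);
    for (arma::uword a = 0; a < K; ++a) {
      const long oy = (long)a * rate - pt;
      const long i0 = std::max(0L, -oy), i1 = std::min((long)Ho, (long)H - oy);
      if (i1 <= i0) continue;
      for (arma::uword t = 0; t < Kw; ++t) {
        const long ox = (long)t * rate - pl;
        const long j0 = std::max(0L, -ox), j1 = std::min((long)Wo, (long)W - ox);
        if (j1 <= j0) continue;
        Xs.zeros();
        for (arma::uword ci = 0; ci < Ci; ++ci) {
          const double* xc = xp + ((n * Ci + ci) * W) * H;
          double* xsc = Xs.colptr(ci);
          for (long j = j0; j < j1; ++j)
            std::memcpy(xsc + j * Ho + i0, xc + (j + ox) * H + (i0 + oy),
                        sizeof(double) * (i1 - i0));
        }
        for (arma::uword ci = 0; ci < Ci; ++ci)
          for (arma::uword co = 0; co < Co; ++co)
            Wab(ci, co) = w[a + t * K + ci * K * Kw + co * K * Kw * Ci];
        GWab = Xs.t() * Gm;
        for (arma::uword ci = 0; ci < Ci; ++ci)
          for (arma::uword co = 0; co < Co; ++co)
            gw[a + t * K + ci * K * Kw + co * K * Kw * Ci] += GWab(ci, co);
        GXs = Gm * Wab.t();
        for (arma::uword ci = 0; ci < Ci; ++ci) {
          double* gxc = gxp + ((n * Ci + ci) * W) * H;
          const double* gsc = GXs.colptr(ci);
          for (long j = j0; j < j1; ++j) {
            double* dst = gxc + (j + ox) * H + (i0 + oy);
            const double* src = gsc + j * Ho + i0;
            for (long i = 0; i < i1 - i0; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
  for (arma::uword co = 0; co < Co; ++co) gb[co] = gbacc(co);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2.  idx holds the within-image linear index of the
// argmax so the backward pass can scatter gradients; ties resolve to the
// first position in column-major order.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  const arma::uword H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  if (H % 2 || W % 2) stop("max pooling requires even spatial dimensions, got %d x %d",
                           (int)H, (int)W);
  const arma::uword Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  idx.attr("dim") = y.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double* xc = xp + ((n * C + c) * W) * H;
      const arma::uword base = ((n * C + c) * Wo) * Ho;
      for (arma::uword j = 0; j < Wo; ++j)
        for (arma::uword i = 0; i < Ho; ++i) {
          arma::uword best = (2 * j) * H + 2 * i;
          double bv = xc[best];
          const arma::uword cand[3] = {best + 1, best + H, best + H + 1};
          for (int q = 0; q < 3; ++q)
            if (xc[cand[q]] > bv) { bv = xc[cand[q]]; best = cand[q]; }
          yp[base + j * Ho + i] = bv;
          ip[base + j * Ho + i] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx, int H, int W) {
  const arma::uword Ho = dim4(gy, 0), Wo = dim4(gy, 1), C = dim4(gy, 2), N = dim4(gy, 3);
  NumericVector gx((double)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  double* gxp = gx.begin();
  const double* gyp = gy.begin();
  const int* ip = idx.begin();
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      double* gxc = gxp + ((n * C + c) * (arma::uword)W) * H;
      const arma::uword base = ((n * C + c) * Wo) * Ho;
      for (arma::uword k = 0; k < Ho * Wo; ++k)
        gxc[ip[base + k]] += gyp[base + k];
    }
  return gx;
}

// Insert zeros between pixels: output (2H-1, 2W-1), x at even positions.
// Composing with a padded convolution of the flipped kernel yields the
// stride-2 transposed convolution.
// [[Rcpp::export]]
NumericVector cpp_upsample_zeros(NumericVector x) {
  const arma::uword H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  const arma::uword Hu = 2 * H - 1, Wu = 2 * W - 1;
  NumericVector y(Hu * Wu * C * N);
  y.attr("dim") = IntegerVector::create(Hu, Wu, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double* xc = xp + ((n * C + c) * W) * H;
      double* yc = yp + ((n * C + c) * Wu) * Hu;
      for (arma::uword j = 0; j < W; ++j)
        for (arma::uword i = 0; i < H; ++i)
          yc[(2 * j) * Hu + 2 * i] = xc[j * H + i];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_zeros_bwd(NumericVector gy) {
  const arma::uword Hu = dim4(gy, 0), Wu = dim4(gy, 1), C = dim4(gy, 2), N = dim4(gy, 3);
  const arma::uword H = (Hu + 1) / 2, W = (Wu + 1) / 2;
  NumericVector gx(H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double* gyc = gyp + ((n * C + c) * Wu) * Hu;
      double* gxc = gxp + ((n * C + c) * W) * H;
      for (arma::uword j = 0; j < W; ++j)
        for (arma::uword i = 0; i < H; ++i)
          gxc[j * H + i] = gyc[(2 * j) * Hu + 2 * i];
    }
  return gx;
}
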