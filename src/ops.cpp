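#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Feature maps are stored as R arrays with dim (C, H, W, N), channel fastest.
// All kernels below follow that layout; indices are 0-based internally.

static inline R_xlen_t idx4(int c, int h, int w, int n, int C, int H, int W) {
  return ((R_xlen_t)n * W + w) * H * C + (R_xlen_t)h * C + c;
}

// im2col: (C,H,W,N) -> (C*k*k, Ho*Wo*N) with patch element order c fastest,
// then kx (col offset), then ky (row offset). Zero padding.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims, int k,
                         int stride, int pad) {
  int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix col((R_xlen_t)C * k * k, (R_xlen_t)Ho * Wo * N);
  double *pc = col.begin();
  const double *px = x.begin();
  R_xlen_t colidx = 0;
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double *dst = pc + colidx * (R_xlen_t)C * k * k;
        for (int ky = 0; ky < k; ++ky) {
          int hin = ho * stride - pad + ky;
          for (int kx = 0; kx < k; ++kx) {
            int win = wo * stride - pad + kx;
            double *d = dst + ((R_xlen_t)ky * k + kx) * C;
            if (hin < 0 || hin >= H || win < 0 || win >= W) {
              for (int c = 0; c < C; ++c) d[c] = 0.0;
            } else {
              const double *s = px + idx4(0, hin, win, n, C, H, W);
              for (int c = 0; c < C; ++c) d[c] = s[c];
            }
          }
        }
        ++colidx;
      }
  return col;
}

// col2im: scatter-add the column gradient back onto the input layout.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix col, IntegerVector dims, int k,
                         int stride, int pad) {
  int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)C * H * W * N);
  double *px = x.begin();
  const double *pc = col.begin();
  R_xlen_t colidx = 0;
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double *src = pc + colidx * (R_xlen_t)C * k * k;
        for (int ky = 0; ky < k; ++ky) {
          int hin = ho * stride - pad + ky;
          if (hin < 0 || hin >= H) continue;
          for (int kx = 0; kx < k; ++kx) {
            int win = wo * stride - pad + kx;
            if (win < 0 || win >= W) continue;
            const double *s = src + ((R_xlen_t)ky * k + kx) * C;
            double *d = px + idx4(0, hin, win, n, C, H, W);
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
        ++colidx;
      }
  x.attr("dim") = dims;
  return x;
}

// max pooling, returns flat 1-based argmax indices for the backward pass
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, IntegerVector dims, int k, int stride,
                 int pad) {
  int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)C * Ho * Wo * N);
  NumericVector amax((R_xlen_t)C * Ho * Wo * N);
  const double *px = x.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double best = -DBL_MAX; R_xlen_t bidx = -1;
          for (int ky = 0; ky < k; ++ky) {
            int hin = ho * stride - pad + ky;
            if (hin < 0 || hin >= H) continue;
            for (int kx = 0; kx < k; ++kx) {
              int win = wo * stride - pad + kx;
              if (win < 0 || win >= W) continue;
              R_xlen_t ii = idx4(c, hin, win, n, C, H, W);
              if (px[ii] > best) { best = px[ii]; bidx = ii; }
            }
          }
          out[o] = best; amax[o] = (double)(bidx + 1); ++o;
        }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector g, NumericVector argmax,
                              IntegerVector dims) {
  NumericVector dx((R_xlen_t)dims[0] * dims[1] * dims[2] * dims[3]);
  for (R_xlen_t i = 0; i < g.size(); ++i)
    dx[(R_xlen_t)argmax[i] - 1] += g[i];
  dx.attr("dim") = dims;
  return dx;
}

// depth-to-space: in (C*r^2, H, W, N) -> out (C, rH, rW, N) with
// out[c, h*r+i, w*r+j] = in[c*r^2 + i*r + j, h, w]   (0-based)
// [[Rcpp::export]]
NumericVector cpp_pixel_shuffle(NumericVector x, IntegerVector dims, int r) {
  int Cin = dims[0], H = dims[1], W = dims[2], N = dims[3];
  int C = Cin / (r * r), Ho = H * r, Wo = W * r;
  NumericVector out((R_xlen_t)C * Ho * Wo * N);
  const double *px = x.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int c = 0; c < C; ++c)
          for (int i = 0; i < r; ++i)
            for (int j = 0; j < r; ++j)
              po[idx4(c, h * r + i, w * r + j, n, C, Ho, Wo)] =
                px[idx4(c * r * r + i * r + j, h, w, n, Cin, H, W)];
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return out;
}

// space-to-depth, the exact inverse of cpp_pixel_shuffle
// [[Rcpp::export]]
NumericVector cpp_pixel_unshuffle(NumericVector x, IntegerVector dims, int r) {
  int C = dims[0], Ho = dims[1], Wo = dims[2], N = dims[3];
  int Cin = C * r * r, H = Ho / r, W = Wo / r;
  NumericVector out((R_xlen_t)Cin * H * W * N);
  const double *px = x.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int c = 0; c < C; ++c)
          for (int i = 0; i < r; ++i)
            for (int j = 0; j < r; ++j)
              po[idx4(c * r * r + i * r + j, h, w, n, Cin, H, W)] =
                px[idx4(c, h * r + i, w * r + j, n, C, Ho, Wo)];
  out.attr("dim") = IntegerVector::create(Cin, H, W, N);
  return out;
}

// global max pool over H,W per (channel, image): out (C,N) + 1-based argmax
// [[Rcpp::export]]
List cpp_gmp(NumericVector x, IntegerVector dims) {
  int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  NumericMatrix out(C, N), amax(C, N);
  const double *px = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double best = -DBL_MAX; R_xlen_t bidx = -1;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          R_xlen_t ii = idx4(c, h, w, n, C, H, W);
          if (px[ii] > best) { best = px[ii]; bidx = ii; }
        }
      out(c, n) = best; amax(c, n) = (double)(bidx + 1);
    }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// max over channels: out (1,H,W,N) + 1-based argmax into x
// [[Rcpp::export]]
List cpp_chanmax(NumericVector x, IntegerVector dims) {
  int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  R_xlen_t M = (R_xlen_t)H * W * N;
  NumericVector out(M), amax(M);
  const double *px = x.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *s = px + m * C;
    double best = s[0]; int bc = 0;
    for (int c = 1; c < C; ++c) if (s[c] > best) { best = s[c]; bc = c; }
    out[m] = best; amax[m] = (double)(m * C + bc + 1);
  }
  out.attr("dim") = IntegerVector::create(1, H, W, N);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// adaptive average pooling to a (Ho,Wo) grid with uniform bin edges
// [[Rcpp::export]]
NumericVector cpp_adaptive_avgpool(NumericVector x, IntegerVector dims,
                                   int Ho, int Wo) {
  int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  NumericVector out((R_xlen_t)C * Ho * Wo * N);
  const double *px = x.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo) {
      int w0 = (int)std::floor((double)wo * W / Wo);
      int w1 = (int)std::ceil((double)(wo + 1) * W / Wo);
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = (int)std::floor((double)ho * H / Ho);
        int h1 = (int)std::ceil((double)(ho + 1) * H / Ho);
        double inv = 1.0 / ((h1 - h0) * (w1 - w0));
        for (int c = 0; c < C; ++c) {
          double acc = 0.0;
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h)
              acc += px[idx4(c, h, w, n, C, H, W)];
          po[idx4(c, ho, wo, n, C, Ho, Wo)] = acc * inv;
        }
      }
    }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_adaptive_avgpool_bwd(NumericVector g, IntegerVector dims,
                                       int Ho, int Wo) {
  int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  NumericVector dx((R_xlen_t)C * H * W * N);
  const double *pg = g.begin();
  double *pd = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo) {
      int w0 = (int)std::floor((double)wo * W / Wo);
      int w1 = (int)std::ceil((double)(wo + 1) * W / Wo);
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = (int)std::floor((double)ho * H / Ho);
        int h1 = (int)std::ceil((double)(ho + 1) * H / Ho);
        double inv = 1.0 / ((h1 - h0) * (w1 - w0));
        for (int c = 0; c < C; ++c) {
          double gv = pg[idx4(c, ho, wo, n, C, Ho, Wo)] * inv;
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h)
              pd[idx4(c, h, w, n, C, H, W)] += gv;
        }
      }
    }
  dx.attr("dim") = dims;
  return dx;
}

// rasterize a polyline into an (H,W,3) image (column-major, H fastest),
// clipping rows to [row_lo, row_hi] (1-based inclusive). Draws 1px-wide
// vertical spans between consecutive samples so steep segments stay solid.
// [[Rcpp::export]]
void cpp_draw_polyline(NumericVector img, int H, int W, NumericVector xs,
                       NumericVector ys, NumericVector rgb, int row_lo,
                       int row_hi) {
  int npts = xs.size();
  double *p = img.begin();
  int lo = std::max(row_lo - 1, 0), hi = std::min(row_hi - 1, H - 1);
  for (int i = 0; i < npts - 1; ++i) {
    int x0 = (int)std::lround(xs[i]) - 1, x1 = (int)std::lround(xs[i + 1]) - 1;
    double y0 = ys[i], y1 = ys[i + 1];
    if (x1 < x0) { std::swap(x0, x1); std::swap(y0, y1); }
    for (int x = x0; x <= x1; ++x) {
      if (x < 0 || x >= W) continue;
      double t0 = (x1 == x0) ? 0.0 : (double)(x - x0) / (x1 - x0);
      double t1 = (x1 == x0) ? 1.0 : (double)(x + 1 - x0) / (x1 - x0);
      if (t1 > 1.0) t1 = 1.0;
      double ya = y0 + (y1 - y0) * t0, yb = y0 + (y1 - y0) * t1;
      int ra = (int)std::lround(std::min(ya, yb)) - 1;
      int rb = (int)std::lround(std::max(ya, yb)) - 1;
      if (ra < lo) ra = lo;
      if (rb > hi) rb = hi;
      for (int r = ra; r <= rb; ++r) {
        R_xlen_t base = (R_xlen_t)x * H + r;
        p[base] = rgb[0];
        p[base + (R_xlen_t)H * W] = rgb[1];
        p[base + 2 * (R_xlen_t)H * W] = rgb[2];
      }
    }
  }
}
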