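#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Feature maps are column-major arrays with dim = c(H, W, C).
// im2col row index = oh + Hout*ow; column index = kh + k*(kw + k*c),
// matching a weight matrix with rows ordered (kh, kw, c).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const int nrow = Hout * Wout;
  const int ncol = k * k * C;
  NumericMatrix out(nrow, ncol);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = px + (R_xlen_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double *col = po + (R_xlen_t)nrow * (kh + k * (kw + k * c));
        for (int ow = 0; ow < Wout; ++ow) {
          const int w = ow * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          const double *src = plane + (R_xlen_t)H * w;
          double *dst = col + (R_xlen_t)Hout * ow;
          for (int oh = 0; oh < Hout; ++oh) {
            const int h = oh * stride - pad + kh;
            if (h >= 0 && h < H) dst[oh] = src[h];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_maxpool(NumericVector x, int H, int W, int C,
                          int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)Hout * Wout * C);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = px + (R_xlen_t)H * W * c;
    double *oplane = po + (R_xlen_t)Hout * Wout * c;
    for (int ow = 0; ow < Wout; ++ow) {
      for (int oh = 0; oh < Hout; ++oh) {
        double m = R_NegInf;
        for (int kw = 0; kw < k; ++kw) {
          const int w = ow * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = oh * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            const double v = plane[h + (R_xlen_t)H * w];
            if (v > m) m = v;
          }
        }
        oplane[oh + (R_xlen_t)Hout * ow] = m;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Hout, Wout, C);
  return out;
}

// Average pooling, zero-padded positions included in the divisor
// (count_include_pad convention).
// [[Rcpp::export]]
NumericVector cpp_avgpool(NumericVector x, int H, int W, int C,
                          int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)Hout * Wout * C);
  const double *px = x.begin();
  double *po = out.begin();
  const double denom = (double)k * k;
  for (int c = 0; c < C; ++c) {
    const double *plane = px + (R_xlen_t)H * W * c;
    double *oplane = po + (R_xlen_t)Hout * Wout * c;
    for (int ow = 0; ow < Wout; ++ow) {
      for (int oh = 0; oh < Hout; ++oh) {
        double s = 0.0;
        for (int kw = 0; kw < k; ++kw) {
          const int w = ow * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = oh * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            s += plane[h + (R_xlen_t)H * w];
          }
        }
        oplane[oh + (R_xlen_t)Hout * ow] = s / denom;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Hout, Wout, C);
  return out;
}

// Adaptive average pooling with floor/ceil bin edges, so any output size
// (larger or smaller than the input) is valid.
// [[Rcpp::export]]
NumericVector cpp_adaptive_avgpool(NumericVector x, int H, int W, int C,
                                   int outH, int outW) {
  NumericVector out((R_xlen_t)outH * outW * C);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = px + (R_xlen_t)H * W * c;
    double *oplane = po + (R_xlen_t)outH * outW * c;
    for (int ow = 0; ow < outW; ++ow) {
      const int w0 = (int)std::floor((double)ow * W / outW);
      const int w1 = (int)std::ceil((double)(ow + 1) * W / outW);
      for (int oh = 0; oh < outH; ++oh) {
        const int h0 = (int)std::floor((double)oh * H / outH);
        const int h1 = (int)std::ceil((double)(oh + 1) * H / outH);
        double s = 0.0;
        for (int w = w0; w < w1; ++w)
          for (int h = h0; h < h1; ++h)
            s += plane[h + (R_xlen_t)H * w];
        oplane[oh + (R_xlen_t)outH * ow] = s / ((w1 - w0) * (h1 - h0));
      }
    }
  }
  out.attr("dim") = IntegerVector::create(outH, outW, C);
  return out;
}

// Separable 1D convolution along one axis of a column-major (d1, d2, d3)
// array with zero padding; `w` has odd length.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector x, int d1, int d2, int d3,
                                NumericVector w, int axis) {
  const int r = (w.size() - 1) / 2;
  NumericVector out((R_xlen_t)d1 * d2 * d3);
  const double *px = x.begin();
  const double *pw = w.begin();
  double *po = out.begin();
  const int n = (axis == 1) ? d1 : (axis == 2) ? d2 : d3;
  const R_xlen_t stride = (axis == 1) ? 1
                        : (axis == 2) ? (R_xlen_t)d1
                        : (R_xlen_t)d1 * d2;
  // base offsets of each line (all index combinations of the other axes)
  for (int c = 0; c < ((axis == 3) ? 1 : d3); ++c) {
    for (int b = 0; b < ((axis == 2) ? 1 : d2); ++b) {
      for (int a = 0; a < ((axis == 1) ? 1 : d1); ++a) {
        const R_xlen_t base = a + (R_xlen_t)d1 * b + (R_xlen_t)d1 * d2 * c;
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          const int j0 = std::max(0, i - r);
          const int j1 = std::min(n - 1, i + r);
          for (int j = j0; j <= j1; ++j) {
            s += px[base + stride * j] * pw[j - i + r];
          }
          po[base + stride * i] = s;
        }
      }
    }
  }
  return out;
}

// Co-occurrence counts for several offsets in one pass. `binned` is a
// column-major (d1, d2, d3) integer array with 0 outside the ROI;
// `offsets` has one (dx, dy, dz) row per direction. Returns an
// (n_bins * n_bins) x n_offsets matrix of raw (un-symmetrized) counts,
// column-major within each direction: count[a, b] at (a-1)*n_bins + b.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerVector binned, int d1, int d2, int d3,
                              IntegerMatrix offsets, int n_bins) {
  const int k = offsets.nrow();
  NumericMatrix out(n_bins * n_bins, k);
  const int *g = binned.begin();
  for (int o = 0; o < k; ++o) {
    const int dx = offsets(o, 0), dy = offsets(o, 1), dz = offsets(o, 2);
    double *cnt = &out(0, o);
    for (int z = std::max(0, -dz); z < d3 - std::max(0, dz); ++z) {
      for (int y = std::max(0, -dy); y < d2 - std::max(0, dy); ++y) {
        const R_xlen_t base = (R_xlen_t)d1 * (y + (R_xlen_t)d2 * z);
        const R_xlen_t nbase =
          (R_xlen_t)d1 * ((y + dy) + (R_xlen_t)d2 * (z + dz));
        for (int x = std::max(0, -dx); x < d1 - std::max(0, dx); ++x) {
          const int a = g[base + x];
          if (a == 0) continue;
          const int b = g[nbase + x + dx];
          if (b == 0) continue;
          cnt[(a - 1) * n_bins + (b - 1)] += 1.0;
        }
      }
    }
  }
  return out;
}

// Connected zones of equal gray level (26-connectivity in 3D).
// `gray` is a column-major (d1, d2, d3) integer array with 0 outside the
// ROI. Returns a matrix with one row per zone: (gray level, zone size).
// [[Rcpp::export]]
IntegerMatrix cpp_gray_zones(IntegerVector gray, int d1, int d2, int d3) {
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<char> seen(n, 0);
  std::vector<int> glev, zsize;
  std::vector<R_xlen_t> stack;
  const int *g = gray.begin();
  for (R_xlen_t start = 0; start < n; ++start) {
    if (seen[start] || g[start] == 0) continue;
    const int level = g[start];
    int size = 0;
    seen[start] = 1;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      const int z = (int)(v / ((R_xlen_t)d1 * d2));
      const int rem = (int)(v % ((R_xlen_t)d1 * d2));
      const int y = rem / d1;
      const int x = rem % d1;
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= d3) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= d2) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx;
            if (xx < 0 || xx >= d1) continue;
            const R_xlen_t u = xx + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * zz);
            if (!seen[u] && g[u] == level) {
              seen[u] = 1;
              stack.push_back(u);
            }
          }
        }
      }
    }
    glev.push_back(level);
    zsize.push_back(size);
  }
  IntegerMatrix out(glev.size(), 2);
  for (size_t i = 0; i < glev.size(); ++i) {
    out(i, 0) = glev[i];
    out(i, 1) = zsize[i];
  }
  colnames(out) = CharacterVector::create("gray", "size");
  return out;
}
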