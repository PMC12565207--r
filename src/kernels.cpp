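#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Array layout throughout: R arrays with dim c(C, D, H, W), column-major,
// so the channel index is fastest. Voxel (d,h,w) of channel c sits at
//   c + C*(d + D*(h + H*w)).
// Convolution weights: dim c(Cout, Cin/groups, K, K, K).
// All loops are single-threaded for bit-reproducibility.

static inline R_xlen_t vox(int C, int D, int H, int d, int h, int w) {
  return (R_xlen_t)C * (d + (R_xlen_t)D * (h + (R_xlen_t)H * w));
}

// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector x, IntegerVector xdim,
                         NumericVector wgt, int K, int stride, int pad,
                         int groups) {
  const int Cin = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Cing = Cin / groups;
  const int Cout = (int)(wgt.size() / ((R_xlen_t)Cing * K * K * K));
  const int CoutG = Cout / groups;
  const int Do = (D + 2 * pad - K) / stride + 1;
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  NumericVector y((R_xlen_t)Cout * Do * Ho * Wo);
  const double *xp = x.begin(), *wp = wgt.begin();
  double *yp = y.begin();
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od) {
        double *yv = yp + vox(Cout, Do, Ho, od, oh, ow);
        for (int kw = 0; kw < K; ++kw) {
          int iw = ow * stride + kw - pad;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            int ih = oh * stride + kh - pad;
            if (ih < 0 || ih >= H) continue;
            for (int kd = 0; kd < K; ++kd) {
              int id = od * stride + kd - pad;
              if (id < 0 || id >= D) continue;
              const double *xv = xp + vox(Cin, D, H, id, ih, iw);
              const R_xlen_t koff = kd + (R_xlen_t)K * (kh + (R_xlen_t)K * kw);
              for (int g = 0; g < groups; ++g) {
                for (int ci = 0; ci < Cing; ++ci) {
                  const double xval = xv[g * Cing + ci];
                  if (xval == 0.0) continue;
                  const double *wv = wp + (R_xlen_t)Cout * (ci + (R_xlen_t)Cing * koff);
                  double *yg = yv + g * CoutG;
                  const double *wg = wv + g * CoutG;
                  for (int co = 0; co < CoutG; ++co) yg[co] += wg[co] * xval;
                }
              }
            }
          }
        }
      }
  y.attr("dim") = IntegerVector::create(Cout, Do, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_grad_input(NumericVector gy, IntegerVector ydim,
                                    NumericVector wgt, IntegerVector xdim,
                                    int K, int stride, int pad, int groups) {
  const int Cin = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Cout = ydim[0], Do = ydim[1], Ho = ydim[2], Wo = ydim[3];
  const int Cing = Cin / groups, CoutG = Cout / groups;
  NumericVector gx((R_xlen_t)Cin * D * H * W);
  const double *gyp = gy.begin(), *wp = wgt.begin();
  double *gxp = gx.begin();
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od) {
        const double *gyv = gyp + vox(Cout, Do, Ho, od, oh, ow);
        for (int kw = 0; kw < K; ++kw) {
          int iw = ow * stride + kw - pad;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            int ih = oh * stride + kh - pad;
            if (ih < 0 || ih >= H) continue;
            for (int kd = 0; kd < K; ++kd) {
              int id = od * stride + kd - pad;
              if (id < 0 || id >= D) continue;
              double *gxv = gxp + vox(Cin, D, H, id, ih, iw);
              const R_xlen_t koff = kd + (R_xlen_t)K * (kh + (R_xlen_t)K * kw);
              for (int g = 0; g < groups; ++g) {
                for (int ci = 0; ci < Cing; ++ci) {
                  const double *wv = wp + (R_xlen_t)Cout * (ci + (R_xlen_t)Cing * koff) + g * CoutG;
                  const double *gyg = gyv + g * CoutG;
                  double acc = 0.0;
                  for (int co = 0; co < CoutG; ++co) acc += wv[co] * gyg[co];
                  gxv[g * Cing + ci] += acc;
                }
              }
            }
          }
        }
      }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_grad_weight(NumericVector x, IntegerVector xdim,
                                     NumericVector gy, IntegerVector ydim,
                                     int K, int stride, int pad, int groups) {
  const int Cin = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Cout = ydim[0], Do = ydim[1], Ho = ydim[2], Wo = ydim[3];
  const int Cing = Cin / groups, CoutG = Cout / groups;
  NumericVector gw((R_xlen_t)Cout * Cing * K * K * K);
  const double *xp = x.begin(), *gyp = gy.begin();
  double *gwp = gw.begin();
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od) {
        const double *gyv = gyp + vox(Cout, Do, Ho, od, oh, ow);
        for (int kw = 0; kw < K; ++kw) {
          int iw = ow * stride + kw - pad;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            int ih = oh * stride + kh - pad;
            if (ih < 0 || ih >= H) continue;
            for (int kd = 0; kd < K; ++kd) {
              int id = od * stride + kd - pad;
              if (id < 0 || id >= D) continue;
              const double *xv = xp + vox(Cin, D, H, id, ih, iw);
              const R_xlen_t koff = kd + (R_xlen_t)K * (kh + (R_xlen_t)K * kw);
              for (int g = 0; g < groups; ++g) {
                for (int ci = 0; ci < Cing; ++ci) {
                  const double xval = xv[g * Cing + ci];
                  if (xval == 0.0) continue;
                  double *gwv = gwp + (R_xlen_t)Cout * (ci + (R_xlen_t)Cing * koff) + g * CoutG;
                  const double *gyg = gyv + g * CoutG;
                  for (int co = 0; co < CoutG; ++co) gwv[co] += gyg[co] * xval;
                }
              }
            }
          }
        }
      }
  gw.attr("dim") = IntegerVector::create(Cout, Cing, K, K, K);
  return gw;
}

// Transposed 2x2x2 stride-2 convolution (non-overlapping upsampling).
// Weight dim: c(Cout, Cin, 2, 2, 2).

// [[Rcpp::export]]
NumericVector cpp_upconv2(NumericVector x, IntegerVector xdim, NumericVector wgt,
                          int Cout) {
  const int Cin = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  NumericVector y((R_xlen_t)Cout * 2 * D * 2 * H * 2 * W);
  const double *xp = x.begin(), *wp = wgt.begin();
  double *yp = y.begin();
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const double *xv = xp + vox(Cin, D, H, d, h, w);
        for (int kw = 0; kw < 2; ++kw)
          for (int kh = 0; kh < 2; ++kh)
            for (int kd = 0; kd < 2; ++kd) {
              double *yv = yp + vox(Cout, Do, Ho, 2 * d + kd, 2 * h + kh, 2 * w + kw);
              const R_xlen_t koff = kd + 2 * (kh + 2 * kw);
              for (int ci = 0; ci < Cin; ++ci) {
                const double xval = xv[ci];
                if (xval == 0.0) continue;
                const double *wv = wp + (R_xlen_t)Cout * (ci + (R_xlen_t)Cin * koff);
                for (int co = 0; co < Cout; ++co) yv[co] += wv[co] * xval;
              }
            }
      }
  y.attr("dim") = IntegerVector::create(Cout, Do, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upconv2_grad_input(NumericVector gy, IntegerVector ydim,
                                     NumericVector wgt, IntegerVector xdim) {
  const int Cin = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Cout = ydim[0], Do = ydim[1], Ho = ydim[2];
  NumericVector gx((R_xlen_t)Cin * D * H * W);
  const double *gyp = gy.begin(), *wp = wgt.begin();
  double *gxp = gx.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        double *gxv = gxp + vox(Cin, D, H, d, h, w);
        for (int kw = 0; kw < 2; ++kw)
          for (int kh = 0; kh < 2; ++kh)
            for (int kd = 0; kd < 2; ++kd) {
              const double *gyv = gyp + vox(Cout, Do, Ho, 2 * d + kd, 2 * h + kh, 2 * w + kw);
              const R_xlen_t koff = kd + 2 * (kh + 2 * kw);
              for (int ci = 0; ci < Cin; ++ci) {
                const double *wv = wp + (R_xlen_t)Cout * (ci + (R_xlen_t)Cin * koff);
                double acc = 0.0;
                for (int co = 0; co < Cout; ++co) acc += wv[co] * gyv[co];
                gxv[ci] += acc;
              }
            }
      }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upconv2_grad_weight(NumericVector x, IntegerVector xdim,
                                      NumericVector gy, IntegerVector ydim) {
  const int Cin = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Cout = ydim[0], Do = ydim[1], Ho = ydim[2];
  NumericVector gw((R_xlen_t)Cout * Cin * 8);
  const double *xp = x.begin(), *gyp = gy.begin();
  double *gwp = gw.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const double *xv = xp + vox(Cin, D, H, d, h, w);
        for (int kw = 0; kw < 2; ++kw)
          for (int kh = 0; kh < 2; ++kh)
            for (int kd = 0; kd < 2; ++kd) {
              const double *gyv = gyp + vox(Cout, Do, Ho, 2 * d + kd, 2 * h + kh, 2 * w + kw);
              const R_xlen_t koff = kd + 2 * (kh + 2 * kw);
              for (int ci = 0; ci < Cin; ++ci) {
                const double xval = xv[ci];
                if (xval == 0.0) continue;
                double *gwv = gwp + (R_xlen_t)Cout * (ci + (R_xlen_t)Cin * koff);
                for (int co = 0; co < Cout; ++co) gwv[co] += gyv[co] * xval;
              }
            }
      }
  gw.attr("dim") = IntegerVector::create(Cout, Cin, 2, 2, 2);
  return gw;
}

// 2x2x2 max pooling, stride 2 (even spatial dims assumed).

// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)C * Do * Ho * Wo);
  IntegerVector arg((R_xlen_t)C * Do * Ho * Wo);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ap = arg.begin();
  R_xlen_t oidx = 0;
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od)
        for (int c = 0; c < C; ++c, ++oidx) {
          double best = -INFINITY;
          R_xlen_t bidx = 0;
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd) {
                R_xlen_t idx = c + vox(C, D, H, 2 * od + kd, 2 * oh + kh, 2 * ow + kw);
                if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
              }
          yp[oidx] = best;
          ap[oidx] = (int)bidx; // safe: tensors here stay < 2^31 elements
        }
  y.attr("dim") = IntegerVector::create(C, Do, Ho, Wo);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_grad(NumericVector gy, IntegerVector argmax,
                                IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  double *gxp = gx.begin();
  const double *gyp = gy.begin();
  const int *ap = argmax.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) gxp[ap[i]] += gyp[i];
  gx.attr("dim") = xdim;
  return gx;
}

// Trilinear 2x upsampling, align_corners = FALSE convention:
// input coordinate of output index o is (o + 0.5)/2 - 0.5, clamped.

static void lin_index(int n_out, int n_in, std::vector<int> &i0,
                      std::vector<int> &i1, std::vector<double> &w1) {
  i0.resize(n_out); i1.resize(n_out); w1.resize(n_out);
  for (int o = 0; o < n_out; ++o) {
    double p = (o + 0.5) / 2.0 - 0.5;
    if (p < 0) p = 0;
    if (p > n_in - 1) p = n_in - 1;
    int f = (int)std::floor(p);
    if (f > n_in - 2) f = n_in - 2;
    if (f < 0) f = 0;
    i0[o] = f; i1[o] = (n_in >= 2) ? f + 1 : f;
    w1[o] = p - f;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  std::vector<int> d0, d1, h0, h1, w0, w1;
  std::vector<double> dw, hw, ww;
  lin_index(Do, D, d0, d1, dw);
  lin_index(Ho, H, h0, h1, hw);
  lin_index(Wo, W, w0, w1, ww);
  NumericVector y((R_xlen_t)C * Do * Ho * Wo);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od) {
        double *yv = yp + vox(C, Do, Ho, od, oh, ow);
        for (int bw = 0; bw < 2; ++bw)
          for (int bh = 0; bh < 2; ++bh)
            for (int bd = 0; bd < 2; ++bd) {
              double wt = (bd ? dw[od] : 1 - dw[od]) * (bh ? hw[oh] : 1 - hw[oh]) *
                          (bw ? ww[ow] : 1 - ww[ow]);
              if (wt == 0.0) continue;
              const double *xv = xp + vox(C, D, H, bd ? d1[od] : d0[od],
                                          bh ? h1[oh] : h0[oh], bw ? w1[ow] : w0[ow]);
              for (int c = 0; c < C; ++c) yv[c] += wt * xv[c];
            }
      }
  y.attr("dim") = IntegerVector::create(C, Do, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_grad(NumericVector gy, IntegerVector xdim) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  std::vector<int> d0, d1, h0, h1, w0, w1;
  std::vector<double> dw, hw, ww;
  lin_index(Do, D, d0, d1, dw);
  lin_index(Ho, H, h0, h1, hw);
  lin_index(Wo, W, w0, w1, ww);
  NumericVector gx((R_xlen_t)C * D * H * W);
  const double *gyp = gy.begin();
  double *gxp = gx.begin();
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od) {
        const double *gyv = gyp + vox(C, Do, Ho, od, oh, ow);
        for (int bw = 0; bw < 2; ++bw)
          for (int bh = 0; bh < 2; ++bh)
            for (int bd = 0; bd < 2; ++bd) {
              double wt = (bd ? dw[od] : 1 - dw[od]) * (bh ? hw[oh] : 1 - hw[oh]) *
                          (bw ? ww[ow] : 1 - ww[ow]);
              if (wt == 0.0) continue;
              double *gxv = gxp + vox(C, D, H, bd ? d1[od] : d0[od],
                                      bh ? h1[oh] : h0[oh], bw ? w1[ow] : w0[ow]);
              for (int c = 0; c < C; ++c) gxv[c] += wt * gyv[c];
            }
      }
  gx.attr("dim") = xdim;
  return gx;
}

// Affine resampling of a multi-channel volume by an inverse voxel map:
// for output voxel p (0-based), source coordinate q = M (p - ctr) + ctr + t.
// mode 0 = trilinear, 1 = nearest; out-of-field -> 0.

// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector x, IntegerVector xdim,
                                  NumericMatrix M, NumericVector tr, int mode) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  NumericVector y((R_xlen_t)C * D * H * W);
  const double *xp = x.begin();
  double *yp = y.begin();
  const double cd = (D - 1) / 2.0, ch = (H - 1) / 2.0, cw = (W - 1) / 2.0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const double pd = d - cd, ph = h - ch, pw = w - cw;
        double qd = M(0, 0) * pd + M(0, 1) * ph + M(0, 2) * pw + cd + tr[0];
        double qh = M(1, 0) * pd + M(1, 1) * ph + M(1, 2) * pw + ch + tr[1];
        double qw = M(2, 0) * pd + M(2, 1) * ph + M(2, 2) * pw + cw + tr[2];
        double *yv = yp + vox(C, D, H, d, h, w);
        if (mode == 1) {
          int id = (int)std::lround(qd), ih = (int)std::lround(qh), iw = (int)std::lround(qw);
          if (id < 0 || id >= D || ih < 0 || ih >= H || iw < 0 || iw >= W) continue;
          const double *xv = xp + vox(C, D, H, id, ih, iw);
          for (int c = 0; c < C; ++c) yv[c] = xv[c];
        } else {
          if (qd < -1 || qd > D || qh < -1 || qh > H || qw < -1 || qw > W) continue;
          int d0 = (int)std::floor(qd), h0 = (int)std::floor(qh), w0 = (int)std::floor(qw);
          double fd = qd - d0, fh = qh - h0, fw = qw - w0;
          for (int bw = 0; bw < 2; ++bw)
            for (int bh = 0; bh < 2; ++bh)
              for (int bd = 0; bd < 2; ++bd) {
                int id = d0 + bd, ih = h0 + bh, iw = w0 + bw;
                if (id < 0 || id >= D || ih < 0 || ih >= H || iw < 0 || iw >= W) continue;
                double wt = (bd ? fd : 1 - fd) * (bh ? fh : 1 - fh) * (bw ? fw : 1 - fw);
                if (wt == 0.0) continue;
                const double *xv = xp + vox(C, D, H, id, ih, iw);
                for (int c = 0; c < C; ++c) yv[c] += wt * xv[c];
              }
        }
      }
  y.attr("dim") = xdim;
  return y;
}

// Connected-component labelling of a binary 3-D mask (6 or 26 connectivity).
// Returns integer labels (0 = background) and component sizes.

// [[Rcpp::export]]
List cpp_label_components(IntegerVector mask, IntegerVector mdim, int connectivity) {
  const int D = mdim[0], H = mdim[1], W = mdim[2];
  const R_xlen_t N = (R_xlen_t)D * H * W;
  IntegerVector labels(N);
  const int *mp = mask.begin();
  int *lp = labels.begin();
  std::vector<int> offs_d, offs_h, offs_w;
  for (int dw = -1; dw <= 1; ++dw)
    for (int dh = -1; dh <= 1; ++dh)
      for (int dd = -1; dd <= 1; ++dd) {
        if (dd == 0 && dh == 0 && dw == 0) continue;
        int manh = std::abs(dd) + std::abs(dh) + std::abs(dw);
        if (connectivity == 6 && manh != 1) continue;
        offs_d.push_back(dd); offs_h.push_back(dh); offs_w.push_back(dw);
      }
  std::vector<int> sizes;
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t start = 0; start < N; ++start) {
    if (mp[start] == 0 || lp[start] != 0) continue;
    ++next_label;
    int size = 0;
    stack.clear();
    stack.push_back(start);
    lp[start] = next_label;
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      ++size;
      int d = (int)(idx % D), rest = (int)(idx / D);
      int h = rest % H, w = rest / H;
      for (size_t k = 0; k < offs_d.size(); ++k) {
        int nd = d + offs_d[k], nh = h + offs_h[k], nw = w + offs_w[k];
        if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
        R_xlen_t nidx = nd + (R_xlen_t)D * (nh + (R_xlen_t)H * nw);
        if (mp[nidx] != 0 && lp[nidx] == 0) {
          lp[nidx] = next_label;
          stack.push_back(nidx);
        }
      }
    }
    sizes.push_back(size);
  }
  labels.attr("dim") = mdim;
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}
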