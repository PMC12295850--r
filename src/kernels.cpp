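// Low-level dense kernels for the KidneyNeXt forward/backward passes.
// Tensor layout is column-major (H, W, C, N): index = h + H*(w + W*(c + C*n)).
// Grouped convolution weights are (kh, kw, Cin/groups, Cout).

#include <Rcpp.h>
using namespace Rcpp;

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector bias, int stride, int pad,
                                 int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cg = wd[2], Cout = wd[3];
  const int gCin = C / groups, gCout = Cout / groups;
  if (cg != gCin)
    stop("weight input-channel dim (%d) != channels/groups (%d)", cg, gCin);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const bool hasb = bias.size() > 0;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  for (int n = 0; n < N; ++n) {
    for (int oc = 0; oc < Cout; ++oc) {
      const int ic0 = (oc / gCout) * gCin;
      const double b0 = hasb ? bias[oc] : 0.0;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double acc = b0;
          for (int icl = 0; icl < gCin; ++icl) {
            const int ic = ic0 + icl;
            for (int kx = 0; kx < kw; ++kx) {
              const int iw = ow * stride - pad + kx;
              if (iw < 0 || iw >= W) continue;
              for (int ky = 0; ky < kh; ++ky) {
                const int ih = oh * stride - pad + ky;
                if (ih < 0 || ih >= H) continue;
                acc += x[idx4(ih, iw, ic, n, H, W, C)] *
                       w[ky + kh * (kx + kw * (icl + cg * oc))];
              }
            }
          }
          y[idx4(oh, ow, oc, n, Ho, Wo, Cout)] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad, int groups, bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cg = wd[2], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int gCin = C / groups, gCout = Cout / groups;
  NumericVector dx(x.size());
  NumericVector dw(w.size());
  NumericVector db(has_bias ? Cout : 0);
  for (int n = 0; n < N; ++n) {
    for (int oc = 0; oc < Cout; ++oc) {
      const int ic0 = (oc / gCout) * gCin;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          const double g = dy[idx4(oh, ow, oc, n, Ho, Wo, Cout)];
          if (has_bias) db[oc] += g;
          if (g == 0.0) continue;
          for (int icl = 0; icl < gCin; ++icl) {
            const int ic = ic0 + icl;
            for (int kx = 0; kx < kw; ++kx) {
              const int iw = ow * stride - pad + kx;
              if (iw < 0 || iw >= W) continue;
              for (int ky = 0; ky < kh; ++ky) {
                const int ih = oh * stride - pad + ky;
                if (ih < 0 || ih >= H) continue;
                const int xi = idx4(ih, iw, ic, n, H, W, C);
                const int wi = ky + kh * (kx + kw * (icl + cg * oc));
                dw[wi] += g * x[xi];
                dx[xi] += g * w[wi];
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling; padding positions are ignored (never win). Returns the
// pooled map and the flat argmax index (1-based, into x) per output cell.
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector amax(y.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double best = R_NegInf;
          int bi = -1;
          for (int kx = 0; kx < k; ++kx) {
            const int iw = ow * stride - pad + kx;
            if (iw < 0 || iw >= W) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int ih = oh * stride - pad + ky;
              if (ih < 0 || ih >= H) continue;
              const int xi = idx4(ih, iw, c, n, H, W, C);
              if (x[xi] > best) { best = x[xi]; bi = xi; }
            }
          }
          const int yi = idx4(oh, ow, c, n, Ho, Wo, C);
          y[yi] = best;
          amax[yi] = bi + 1;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(IntegerVector argmax, NumericVector dy,
                                   IntegerVector xdim) {
  NumericVector dx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Average pooling over the valid (non-padded) part of each window, so a
// spatially constant map stays constant at the borders.
// [[Rcpp::export]]
NumericVector cpp_avgpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double acc = 0.0;
          int cnt = 0;
          for (int kx = 0; kx < k; ++kx) {
            const int iw = ow * stride - pad + kx;
            if (iw < 0 || iw >= W) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int ih = oh * stride - pad + ky;
              if (ih < 0 || ih >= H) continue;
              acc += x[idx4(ih, iw, c, n, H, W, C)];
              ++cnt;
            }
          }
          y[idx4(oh, ow, c, n, Ho, Wo, C)] = acc / cnt;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_backward(NumericVector dy, IntegerVector xdim,
                                   int k, int stride, int pad) {
  IntegerVector yd = dy.attr("dim");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          int cnt = 0;
          for (int kx = 0; kx < k; ++kx) {
            const int iw = ow * stride - pad + kx;
            if (iw < 0 || iw >= W) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int ih = oh * stride - pad + ky;
              if (ih >= 0 && ih < H) ++cnt;
            }
          }
          const double g = dy[idx4(oh, ow, c, n, Ho, Wo, C)] / cnt;
          for (int kx = 0; kx < k; ++kx) {
            const int iw = ow * stride - pad + kx;
            if (iw < 0 || iw >= W) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int ih = oh * stride - pad + ky;
              if (ih < 0 || ih >= H) continue;
              dx[idx4(ih, iw, c, n, H, W, C)] += g;
            }
          }
        }
  dx.attr("dim") = xdim;
  return dx;
}
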