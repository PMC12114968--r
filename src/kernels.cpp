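#include <Rcpp.h>
using namespace Rcpp;

// Tensor layout used throughout: a batch of n images of h x w pixels with c
// channels is a numeric matrix with n*h*w rows and c columns.  Row index of
// pixel (i, j) (0-based) of image b is  b*h*w + j*h + i  (column-major within
// an image, image-major across the batch).  This keeps 1x1 convolutions a
// single BLAS matrix product on the R side; the spatial kernels live here.
// Spatial kernels use a clamp-free fast path for interior pixels and handle
// the replicate-padded borders separately.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Depthwise k x k convolution, stride 1, replicate padding (k odd).
// K is (k*k) x c, kernel entries column-major (ki + kj*k); bias length c.
// [[Rcpp::export]]
NumericMatrix cpp_dw_conv_fwd(const NumericMatrix& X, int h, int w, int n,
                              const NumericMatrix& K, const NumericVector& bias) {
  const int c = X.ncol();
  const int kk = K.nrow();
  const int k = (int) std::lround(std::sqrt((double) kk));
  const int p = (k - 1) / 2;
  NumericMatrix Y(X.nrow(), c);
  double kw[49];
  for (int ch = 0; ch < c; ++ch) {
    const double* x = &X(0, ch);
    for (int q = 0; q < kk; ++q) kw[q] = K(q, ch);
    double* y = &Y(0, ch);
    const double b0 = bias[ch];
    for (int b = 0; b < n; ++b) {
      const int off = b * h * w;
      // interior (no clamping)
      for (int j = p; j < w - p; ++j) {
        const double* xc = x + off + (j - p) * h;   // column j-p
        for (int i = p; i < h - p; ++i) {
          double acc = b0;
          const double* xp = xc + (i - p);
          for (int v = 0; v < k; ++v) {
            const double* col = xp + v * h;
            for (int u = 0; u < k; ++u) acc += col[u] * kw[u + v * k];
          }
          y[off + j * h + i] = acc;
        }
      }
      // borders (replicate padding via index clamping)
      for (int j = 0; j < w; ++j) {
        const bool jedge = (j < p || j >= w - p);
        for (int i = 0; i < h; ++i) {
          if (!jedge && i >= p && i < h - p) { i = h - p - 1; continue; }
          double acc = b0;
          for (int v = 0; v < k; ++v) {
            const int xj = clampi(j + v - p, 0, w - 1);
            for (int u = 0; u < k; ++u) {
              const int xi = clampi(i + u - p, 0, h - 1);
              acc += x[off + xj * h + xi] * kw[u + v * k];
            }
          }
          y[off + j * h + i] = acc;
        }
      }
    }
  }
  return Y;
}

// Backward of the above: gradients w.r.t. input, kernel and bias.
// [[Rcpp::export]]
List cpp_dw_conv_bwd(const NumericMatrix& X, const NumericMatrix& G, int h, int w,
                     int n, const NumericMatrix& K) {
  const int c = X.ncol();
  const int kk = K.nrow();
  const int k = (int) std::lround(std::sqrt((double) kk));
  const int p = (k - 1) / 2;
  NumericMatrix dX(X.nrow(), c);
  NumericMatrix dK(kk, c);
  NumericVector db(c);
  double kw[49], dk[49];
  for (int ch = 0; ch < c; ++ch) {
    const double* x = &X(0, ch);
    const double* g = &G(0, ch);
    for (int q = 0; q < kk; ++q) { kw[q] = K(q, ch); dk[q] = 0.0; }
    double* dx = &dX(0, ch);
    double dbacc = 0.0;
    for (int b = 0; b < n; ++b) {
      const int off = b * h * w;
      for (int j = p; j < w - p; ++j) {
        for (int i = p; i < h - p; ++i) {
          const double gi = g[off + j * h + i];
          dbacc += gi;
          double* dxp = dx + off + (j - p) * h + (i - p);
          const double* xp = x + off + (j - p) * h + (i - p);
          for (int v = 0; v < k; ++v) {
            double* dcol = dxp + v * h;
            const double* col = xp + v * h;
            for (int u = 0; u < k; ++u) {
              dcol[u] += gi * kw[u + v * k];
              dk[u + v * k] += gi * col[u];
            }
          }
        }
      }
      for (int j = 0; j < w; ++j) {
        const bool jedge = (j < p || j >= w - p);
        for (int i = 0; i < h; ++i) {
          if (!jedge && i >= p && i < h - p) { i = h - p - 1; continue; }
          const double gi = g[off + j * h + i];
          dbacc += gi;
          for (int v = 0; v < k; ++v) {
            const int xj = clampi(j + v - p, 0, w - 1);
            for (int u = 0; u < k; ++u) {
              const int xi = clampi(i + u - p, 0, h - 1);
              dx[off + xj * h + xi] += gi * kw[u + v * k];
              dk[u + v * k] += gi * x[off + xj * h + xi];
            }
          }
        }
      }
    }
    for (int q = 0; q < kk; ++q) dK(q, ch) = dk[q];
    db[ch] = dbacc;
  }
  return List::create(_["dx"] = dX, _["dk"] = dK, _["db"] = db);
}

// Max pooling.  pad > 0 uses replicate padding (index clamping); output size
// oh = (h + 2*pad - k) / stride + 1.  Returns pooled values and 1-based argmax
// row indices into the input matrix for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericMatrix& X, int h, int w, int n, int k,
                     int stride, int pad) {
  const int c = X.ncol();
  const int oh = (h + 2 * pad - k) / stride + 1;
  const int ow = (w + 2 * pad - k) / stride + 1;
  NumericMatrix Y(n * oh * ow, c);
  IntegerMatrix idx(n * oh * ow, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* x = &X(0, ch);
    double* y = &Y(0, ch);
    int* id = &idx(0, ch);
    for (int b = 0; b < n; ++b) {
      const int off = b * h * w;
      const int ooff = b * oh * ow;
      for (int oj = 0; oj < ow; ++oj) {
        const int j0 = oj * stride - pad;
        const bool jin = (j0 >= 0 && j0 + k <= w);
        for (int oi = 0; oi < oh; ++oi) {
          const int i0 = oi * stride - pad;
          double best = -1e300;
          int bestr = -1;
          if (jin && i0 >= 0 && i0 + k <= h) {
            for (int v = 0; v < k; ++v) {
              const double* col = x + off + (j0 + v) * h + i0;
              for (int u = 0; u < k; ++u) {
                if (col[u] > best) { best = col[u]; bestr = off + (j0 + v) * h + i0 + u; }
              }
            }
          } else {
            for (int v = 0; v < k; ++v) {
              const int xj = clampi(j0 + v, 0, w - 1);
              for (int u = 0; u < k; ++u) {
                const int xi = clampi(i0 + u, 0, h - 1);
                const int r = off + xj * h + xi;
                if (x[r] > best) { best = x[r]; bestr = r; }
              }
            }
          }
          y[ooff + oj * oh + oi] = best;
          id[ooff + oj * oh + oi] = bestr + 1;
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx, _["oh"] = oh, _["ow"] = ow);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& G, const IntegerMatrix& idx,
                              int nrow_in) {
  const int c = G.ncol();
  NumericMatrix dX(nrow_in, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* g = &G(0, ch);
    const int* id = &idx(0, ch);
    double* dx = &dX(0, ch);
    for (int r = 0; r < G.nrow(); ++r) dx[id[r] - 1] += g[r];
  }
  return dX;
}

// Adaptive average pooling to oh x ow (same region convention as the usual
// deep-learning adaptive pool: region bounds floor(i*h/oh) .. ceil((i+1)*h/oh)).
// [[Rcpp::export]]
NumericMatrix cpp_adapt_avgpool_fwd(const NumericMatrix& X, int h, int w, int n,
                                    int oh, int ow) {
  const int c = X.ncol();
  NumericMatrix Y(n * oh * ow, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* x = &X(0, ch);
    double* y = &Y(0, ch);
    for (int b = 0; b < n; ++b) {
      const int off = b * h * w, ooff = b * oh * ow;
      for (int oj = 0; oj < ow; ++oj) {
        const int j0 = (oj * w) / ow, j1 = ((oj + 1) * w + ow - 1) / ow;
        for (int oi = 0; oi < oh; ++oi) {
          const int i0 = (oi * h) / oh, i1 = ((oi + 1) * h + oh - 1) / oh;
          double acc = 0.0;
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i) acc += x[off + j * h + i];
          y[ooff + oj * oh + oi] = acc / ((i1 - i0) * (j1 - j0));
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix cpp_adapt_avgpool_bwd(const NumericMatrix& G, int h, int w, int n,
                                    int oh, int ow) {
  const int c = G.ncol();
  NumericMatrix dX(n * h * w, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* g = &G(0, ch);
    double* dx = &dX(0, ch);
    for (int b = 0; b < n; ++b) {
      const int off = b * h * w, ooff = b * oh * ow;
      for (int oj = 0; oj < ow; ++oj) {
        const int j0 = (oj * w) / ow, j1 = ((oj + 1) * w + ow - 1) / ow;
        for (int oi = 0; oi < oh; ++oi) {
          const int i0 = (oi * h) / oh, i1 = ((oi + 1) * h + oh - 1) / oh;
          const double gi = g[ooff + oj * oh + oi] / ((i1 - i0) * (j1 - j0));
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i) dx[off + j * h + i] += gi;
        }
      }
    }
  }
  return dX;
}

// Fused bias add + ReLU (used after the 1x1 convolutions' BLAS product).
// [[Rcpp::export]]
NumericMatrix cpp_bias_relu(const NumericMatrix& X, const NumericVector& bias) {
  const int c = X.ncol(), nr = X.nrow();
  NumericMatrix Y(nr, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* x = &X(0, ch);
    double* y = &Y(0, ch);
    const double b0 = bias[ch];
    for (int r = 0; r < nr; ++r) {
      const double v = x[r] + b0;
      y[r] = v > 0.0 ? v : 0.0;
    }
  }
  return Y;
}

// ReLU backward from the post-activation output.
// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(const NumericMatrix& Y, const NumericMatrix& G) {
  const int c = Y.ncol(), nr = Y.nrow();
  NumericMatrix dX(nr, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* y = &Y(0, ch);
    const double* g = &G(0, ch);
    double* dx = &dX(0, ch);
    for (int r = 0; r < nr; ++r) dx[r] = y[r] > 0.0 ? g[r] : 0.0;
  }
  return dX;
}

// Inverse-mapped bilinear affine sampling of a single image ((h*w) x c matrix,
// column-major pixels) onto an oh x ow canvas.  Coordinates are centred so a
// horizontal flip of the source commutes exactly with negating the first
// column of M; samples falling outside the source are filled with `fill`.
// Source position of output pixel (i, j):
//   [xs, ys] = M %*% [j - (ow-1)/2, i - (oh-1)/2] + t   (x = column, y = row)
// [[Rcpp::export]]
NumericMatrix cpp_affine_sample(const NumericMatrix& img, int h, int w, int oh,
                                int ow, const NumericMatrix& M,
                                const NumericVector& t, double fill) {
  const int c = img.ncol();
  NumericMatrix out(oh * ow, c);
  const double cx = (ow - 1) / 2.0, cy = (oh - 1) / 2.0;
  const double sx = (w - 1) / 2.0, sy = (h - 1) / 2.0;
  for (int j = 0; j < ow; ++j) {
    const double x = j - cx;
    for (int i = 0; i < oh; ++i) {
      const double y = i - cy;
      const double xs = M(0, 0) * x + M(0, 1) * y + t[0] + sx;
      const double ys = M(1, 0) * x + M(1, 1) * y + t[1] + sy;
      const int r = j * oh + i;
      if (xs < -1.0 || xs > (double) w || ys < -1.0 || ys > (double) h) {
        for (int ch = 0; ch < c; ++ch) out(r, ch) = fill;
        continue;
      }
      const int x0 = (int) std::floor(xs), y0 = (int) std::floor(ys);
      const double fx = xs - x0, fy = ys - y0;
      for (int ch = 0; ch < c; ++ch) {
        const double* im = &img(0, ch);
        double acc = 0.0;
        for (int dv = 0; dv <= 1; ++dv) {
          const int xj = x0 + dv;
          const double wx = dv ? fx : 1.0 - fx;
          if (wx == 0.0) continue;
          for (int du = 0; du <= 1; ++du) {
            const int yi = y0 + du;
            const double wy = du ? fy : 1.0 - fy;
            if (wy == 0.0) continue;
            double v = fill;
            if (xj >= 0 && xj < w && yi >= 0 && yi < h) v = im[xj * h + yi];
            acc += wx * wy * v;
          }
        }
        out(r, ch) = acc;
      }
    }
  }
  return out;
}

// Instance normalisation (affine) forward: per image and channel,
// y = gamma * (x - mean) / sqrt(var + eps) + beta.
// [[Rcpp::export]]
List cpp_instnorm_fwd(const NumericMatrix& X, int h, int w, int n,
                      const NumericVector& gamma, const NumericVector& beta,
                      double eps) {
  const int c = X.ncol();
  const int hw = h * w;
  NumericMatrix Y(X.nrow(), c);
  NumericMatrix Xhat(X.nrow(), c);
  NumericMatrix Isd(n, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* x = &X(0, ch);
    double* y = &Y(0, ch);
    double* xh = &Xhat(0, ch);
    const double g0 = gamma[ch], b0 = beta[ch];
    for (int b = 0; b < n; ++b) {
      const int off = b * hw;
      double s = 0.0, s2 = 0.0;
      for (int r = 0; r < hw; ++r) { const double v = x[off + r]; s += v; s2 += v * v; }
      const double mu = s / hw;
      const double var = s2 / hw - mu * mu;
      const double isd = 1.0 / std::sqrt(var > 0 ? var + eps : eps);
      Isd(b, ch) = isd;
      for (int r = 0; r < hw; ++r) {
        const double xv = (x[off + r] - mu) * isd;
        xh[off + r] = xv;
        y[off + r] = g0 * xv + b0;
      }
    }
  }
  return List::create(_["y"] = Y, _["xhat"] = Xhat, _["isd"] = Isd);
}

// Instance normalisation backward.
// [[Rcpp::export]]
List cpp_instnorm_bwd(const NumericMatrix& Xhat, const NumericMatrix& Isd,
                      const NumericVector& gamma, const NumericMatrix& G,
                      int h, int w, int n) {
  const int c = Xhat.ncol();
  const int hw = h * w;
  NumericMatrix dX(Xhat.nrow(), c);
  NumericVector dg(c), db(c);
  for (int ch = 0; ch < c; ++ch) {
    const double* xh = &Xhat(0, ch);
    const double* g = &G(0, ch);
    double* dx = &dX(0, ch);
    const double g0 = gamma[ch];
    double dgacc = 0.0, dbacc = 0.0;
    for (int b = 0; b < n; ++b) {
      const int off = b * hw;
      double m1 = 0.0, m2 = 0.0;
      for (int r = 0; r < hw; ++r) {
        const double gv = g[off + r];
        dgacc += gv * xh[off + r];
        dbacc += gv;
        m1 += gv;
        m2 += gv * xh[off + r];
      }
      m1 = g0 * m1 / hw;
      m2 = g0 * m2 / hw;
      const double isd = Isd(b, ch);
      for (int r = 0; r < hw; ++r) {
        dx[off + r] = (g0 * g[off + r] - m1 - xh[off + r] * m2) * isd;
      }
    }
    dg[ch] = dgacc; db[ch] = dbacc;
  }
  return List::create(_["dx"] = dX, _["dg"] = dg, _["db"] = db);
}

// Fused spatial ops of one inception module: depthwise 3x3, depthwise 5x5
// and 3x3/stride-1 max pooling over the same input, one read per pixel
// window.  All outputs keep the input's spatial size (replicate padding).
// [[Rcpp::export]]
List cpp_incspatial_fwd(const NumericMatrix& X, int h, int w, int n,
                        const NumericMatrix& K3, const NumericVector& b3,
                        const NumericMatrix& K5, const NumericVector& b5) {
  const int c = X.ncol();
  NumericMatrix D3(X.nrow(), c), D5(X.nrow(), c), MP(X.nrow(), c);
  IntegerMatrix MPI(X.nrow(), c);
  double k3[9], k5[25];
  for (int ch = 0; ch < c; ++ch) {
    const double* x = &X(0, ch);
    for (int q = 0; q < 9; ++q) k3[q] = K3(q, ch);
    for (int q = 0; q < 25; ++q) k5[q] = K5(q, ch);
    const double c3 = b3[ch], c5 = b5[ch];
    double* d3 = &D3(0, ch);
    double* d5 = &D5(0, ch);
    double* mp = &MP(0, ch);
    int* mpi = &MPI(0, ch);
    for (int b = 0; b < n; ++b) {
      const int off = b * h * w;
      for (int j = 0; j < w; ++j) {
        const bool jin = (j >= 2 && j < w - 2);
        for (int i = 0; i < h; ++i) {
          double a3 = c3, a5 = c5, best = -1e300;
          int bestr = -1;
          if (jin && i >= 2 && i < h - 2) {
            const double* xp = x + off + (j - 2) * h + (i - 2);
            for (int v = 0; v < 5; ++v) {
              const double* col = xp + v * h;
              for (int u = 0; u < 5; ++u) a5 += col[u] * k5[u + v * 5];
            }
            const double* xq = xp + h + 1;   // 3x3 window origin
            for (int v = 0; v < 3; ++v) {
              const double* col = xq + v * h;
              for (int u = 0; u < 3; ++u) {
                a3 += col[u] * k3[u + v * 3];
                if (col[u] > best) {
                  best = col[u];
                  bestr = off + (j - 1 + v) * h + (i - 1 + u);
                }
              }
            }
          } else {
            for (int v = 0; v < 5; ++v) {
              const int xj = clampi(j + v - 2, 0, w - 1);
              for (int u = 0; u < 5; ++u) {
                const int xi = clampi(i + u - 2, 0, h - 1);
                a5 += x[off + xj * h + xi] * k5[u + v * 5];
              }
            }
            for (int v = 0; v < 3; ++v) {
              const int xj = clampi(j + v - 1, 0, w - 1);
              for (int u = 0; u < 3; ++u) {
                const int xi = clampi(i + u - 1, 0, h - 1);
                const int r = off + xj * h + xi;
                a3 += x[r] * k3[u + v * 3];
                if (x[r] > best) { best = x[r]; bestr = r; }
              }
            }
          }
          const int r = off + j * h + i;
          d3[r] = a3; d5[r] = a5; mp[r] = best; mpi[r] = bestr + 1;
        }
      }
    }
  }
  return List::create(_["d3"] = D3, _["d5"] = D5, _["mp"] = MP, _["mpi"] = MPI);
}

// Fused backward: input gradient from both depthwise convolutions plus the
// max-pool scatter, and the kernel/bias gradients, in one pass.
// [[Rcpp::export]]
List cpp_incspatial_bwd(const NumericMatrix& X, const NumericMatrix& G3,
                        const NumericMatrix& G5, const NumericMatrix& GMP,
                        const IntegerMatrix& MPI, const NumericMatrix& K3,
                        const NumericMatrix& K5, int h, int w, int n) {
  const int c = X.ncol();
  NumericMatrix dX(X.nrow(), c), dK3(9, c), dK5(25, c);
  NumericVector db3(c), db5(c);
  double k3[9], k5[25], a3[9], a5[25];
  for (int ch = 0; ch < c; ++ch) {
    const double* x = &X(0, ch);
    const double* g3 = &G3(0, ch);
    const double* g5 = &G5(0, ch);
    const double* gmp = &GMP(0, ch);
    const int* mpi = &MPI(0, ch);
    for (int q = 0; q < 9; ++q) { k3[q] = K3(q, ch); a3[q] = 0.0; }
    for (int q = 0; q < 25; ++q) { k5[q] = K5(q, ch); a5[q] = 0.0; }
    double* dx = &dX(0, ch);
    double s3 = 0.0, s5 = 0.0;
    for (int b = 0; b < n; ++b) {
      const int off = b * h * w;
      for (int j = 0; j < w; ++j) {
        const bool jin = (j >= 2 && j < w - 2);
        for (int i = 0; i < h; ++i) {
          const int r = off + j * h + i;
          const double gi3 = g3[r], gi5 = g5[r];
          s3 += gi3; s5 += gi5;
          dx[mpi[r] - 1] += gmp[r];
          if (jin && i >= 2 && i < h - 2) {
            double* dxp = dx + off + (j - 2) * h + (i - 2);
            const double* xp = x + off + (j - 2) * h + (i - 2);
            for (int v = 0; v < 5; ++v) {
              double* dcol = dxp + v * h;
              const double* col = xp + v * h;
              for (int u = 0; u < 5; ++u) {
                dcol[u] += gi5 * k5[u + v * 5];
                a5[u + v * 5] += gi5 * col[u];
              }
            }
            double* dxq = dxp + h + 1;
            const double* xq = xp + h + 1;
            for (int v = 0; v < 3; ++v) {
              double* dcol = dxq + v * h;
              const double* col = xq + v * h;
              for (int u = 0; u < 3; ++u) {
                dcol[u] += gi3 * k3[u + v * 3];
                a3[u + v * 3] += gi3 * col[u];
              }
            }
          } else {
            for (int v = 0; v < 5; ++v) {
              const int xj = clampi(j + v - 2, 0, w - 1);
              for (int u = 0; u < 5; ++u) {
                const int xi = clampi(i + u - 2, 0, h - 1);
                dx[off + xj * h + xi] += gi5 * k5[u + v * 5];
                a5[u + v * 5] += gi5 * x[off + xj * h + xi];
              }
            }
            for (int v = 0; v < 3; ++v) {
              const int xj = clampi(j + v - 1, 0, w - 1);
              for (int u = 0; u < 3; ++u) {
                const int xi = clampi(i + u - 1, 0, h - 1);
                dx[off + xj * h + xi] += gi3 * k3[u + v * 3];
                a3[u + v * 3] += gi3 * x[off + xj * h + xi];
              }
            }
          }
        }
      }
    }
    for (int q = 0; q < 9; ++q) dK3(q, ch) = a3[q];
    for (int q = 0; q < 25; ++q) dK5(q, ch) = a5[q];
    db3[ch] = s3; db5[ch] = s5;
  }
  return List::create(_["dx"] = dX, _["dk3"] = dK3, _["db3"] = db3,
                      _["dk5"] = dK5, _["db5"] = db5);
}
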