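// Numerical kernels: gemm-based 2-D convolution (im2col/col2im), depthwise
// 3x3 convolution, group normalization, 3x3/s2 max pooling, half-pixel
// bilinear resampling, and the similarity-measure region partitioner.
// All feature maps are column-major double arrays with dims (H, W, C, N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int &H, int &W, int &C,
                             int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H,W,C,N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col, transposed layout: the patch matrix is (Ho*Wo) x (KH*KW*Cin);
// row q = ho + Ho*wo, column r = ki + KH*(kj + KW*ci). Column r matches the
// memory layout of a (KH,KW,Cin,Cout) weight array, so the weight matrix
// needs no copy, and the inner ho loop writes/reads contiguous memory.
// `ld` is the leading dimension of the destination, letting a whole batch
// stack into one matrix (row block per image) for a single gemm.
template <typename T>
static void im2col(const double *x, int H, int W, int C, int KH, int KW,
                   int stride, int pad, int Ho, int Wo, T *Mbase,
                   size_t ld) {
  for (int ci = 0; ci < C; ++ci) {
    const double *xc = x + (size_t)ci * H * W;
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        int r = ki + KH * (kj + KW * ci);
        T *Mcol = Mbase + ld * (size_t)r;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          T *Mq = Mcol + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            std::fill(Mq, Mq + Ho, (T)0);
            continue;
          }
          const double *xcol = xc + (size_t)wi * H;
          if (stride == 1) {
            int ho0 = std::max(0, pad - ki);
            int ho1 = std::min(Ho, H + pad - ki); // hi = ho - pad + ki in [0,H)
            if (ho0 > 0) std::fill(Mq, Mq + ho0, (T)0);
            for (int ho = ho0; ho < ho1; ++ho) Mq[ho] = (T)xcol[ho - pad + ki];
            if (ho1 < Ho) std::fill(Mq + std::max(ho1, ho0), Mq + Ho, (T)0);
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + ki;
              Mq[ho] = (hi < 0 || hi >= H) ? (T)0 : (T)xcol[hi];
            }
          }
        }
      }
    }
  }
}

// scatter-accumulate the gradient of the im2col matrix back into gx
template <typename T>
static void col2im_acc(const T *Gbase, size_t ld, int H, int W, int C,
                       int KH, int KW, int stride, int pad, int Ho, int Wo,
                       double *gx) {
  for (int ci = 0; ci < C; ++ci) {
    double *gc = gx + (size_t)ci * H * W;
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        int r = ki + KH * (kj + KW * ci);
        const T *Gcol = Gbase + ld * (size_t)r;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const T *Gq = Gcol + (size_t)Ho * wo;
          double *gcol = gc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            if (hi >= 0 && hi < H) gcol[hi] += (double)Gq[ho];
          }
        }
      }
    }
  }
}

// Forward convolution. `fp32` switches the gemm (and the patch matrix) to
// single precision — the standard working precision for network training —
// while inputs/outputs stay double; the default path is entirely double.
// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias, int stride,
                             int pad, bool fp32 = false) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  int Ho = (H + 2 * pad - KH) / stride + 1;
  int Wo = (W + 2 * pad - KW) / stride + 1;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  size_t Q = (size_t)Ho * Wo, K = (size_t)KH * KW * Cin;
  if (!fp32) {
    arma::mat Wm(const_cast<double *>(w.begin()), K, Cout, false, true);
    // stack every image's im2col rows so the whole batch is one gemm
    arma::mat M(Q * N, K);
    for (int n = 0; n < N; ++n)
      im2col(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
             Ho, Wo, M.memptr() + Q * (size_t)n, Q * N);
    arma::mat Yall = M * Wm; // (N*Q) x Cout
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c)
        std::copy(Yall.colptr(c) + Q * (size_t)n,
                  Yall.colptr(c) + Q * (size_t)(n + 1),
                  y.begin() + Q * ((size_t)c + (size_t)Cout * n));
  } else {
    arma::fmat Wm(K, Cout);
    std::copy(w.begin(), w.end(), Wm.memptr());
    arma::fmat M(Q * N, K);
    for (int n = 0; n < N; ++n)
      im2col(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
             Ho, Wo, M.memptr() + Q * (size_t)n, Q * N);
    arma::fmat Yall = M * Wm;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c)
        std::copy(Yall.colptr(c) + Q * (size_t)n,
                  Yall.colptr(c) + Q * (size_t)(n + 1),
                  y.begin() + Q * ((size_t)c + (size_t)Cout * n));
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    double *yp = y.begin();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        double bc = b[c];
        double *yc = yp + (size_t)Ho * Wo * (c + (size_t)Cout * n);
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] += bc;
      }
  }
  return y;
}

// fp32 forward that additionally returns the patch matrix as an external
// pointer, so the training backward pass can skip rebuilding it
// [[Rcpp::export]]
List cpp_conv2d_fwd_ws(NumericVector x, NumericVector w,
                       Nullable<NumericVector> bias, int stride, int pad) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  int Ho = (H + 2 * pad - KH) / stride + 1;
  int Wo = (W + 2 * pad - KW) / stride + 1;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  size_t Q = (size_t)Ho * Wo, K = (size_t)KH * KW * Cin;
  arma::fmat Wm(K, Cout);
  std::copy(w.begin(), w.end(), Wm.memptr());
  arma::fmat *M = new arma::fmat(Q * N, K);
  for (int n = 0; n < N; ++n)
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
           Ho, Wo, M->memptr() + Q * (size_t)n, Q * N);
  arma::fmat Yall = (*M) * Wm;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c)
      std::copy(Yall.colptr(c) + Q * (size_t)n,
                Yall.colptr(c) + Q * (size_t)(n + 1),
                y.begin() + Q * ((size_t)c + (size_t)Cout * n));
  if (bias.isNotNull()) {
    NumericVector b(bias);
    double *yp = y.begin();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        double bc = b[c];
        double *yc = yp + (size_t)Ho * Wo * (c + (size_t)Cout * n);
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] += bc;
      }
  }
  XPtr<arma::fmat> ws(M, true);
  return List::create(_["y"] = y, _["ws"] = ws);
}

template <typename MAT>
static void conv_bwd_impl(const MAT &M, const NumericVector &w,
                          const NumericVector &gy, int stride, int pad,
                          int H, int W, int C, int N, int KH, int KW,
                          int Cout, int Ho, int Wo, NumericVector &gx,
                          NumericVector &gw, NumericVector &gb,
                          bool has_bias, bool need_gx) {
  typedef typename MAT::elem_type T;
  size_t Q = (size_t)Ho * Wo, K = (size_t)KH * KW * C;
  MAT Gyall(Q * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      const double *src = gy.begin() + Q * ((size_t)c + (size_t)Cout * n);
      T *dst = Gyall.colptr(c) + Q * (size_t)n;
      for (size_t i = 0; i < Q; ++i) dst[i] = (T)src[i];
    }
  MAT gWm = M.t() * Gyall;
  std::copy(gWm.begin(), gWm.end(), gw.begin());
  if (need_gx) {
    MAT Wm(K, Cout);
    std::copy(w.begin(), w.end(), Wm.memptr());
    MAT Gcol = Gyall * Wm.t(); // (N*Q) x K
    for (int n = 0; n < N; ++n)
      col2im_acc(Gcol.memptr() + Q * (size_t)n, Q * N, H, W, C, KH, KW,
                 stride, pad, Ho, Wo, gx.begin() + (size_t)n * H * W * C);
  }
  if (has_bias) {
    arma::Row<T> s = arma::sum(Gyall, 0);
    for (int c = 0; c < Cout; ++c) gb[c] = (double)s[c];
  }
}

// Backward convolution. `x` may be the saved input (its patch matrix is
// rebuilt) or a workspace external pointer from cpp_conv2d_fwd_ws with the
// input dims passed in `xdim`. `need_gx = false` skips the input-gradient
// gemm (first layer).
// [[Rcpp::export]]
List cpp_conv2d_bwd(SEXP x, NumericVector w, NumericVector gy,
                    int stride, int pad, bool has_bias, bool fp32 = false,
                    Nullable<IntegerVector> xdim = R_NilValue,
                    bool need_gx = true) {
  IntegerVector wd = w.attr("dim");
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1], N = gd[3];
  int H, W, C;
  bool is_ws = (TYPEOF(x) == EXTPTRSXP);
  if (is_ws) {
    IntegerVector d(xdim);
    H = d[0]; W = d[1]; C = d[2]; N = d[3];
  } else {
    NumericVector xv(x);
    get_dims4(xv, H, W, C, N);
  }
  if (C != Cin) stop("conv2d_bwd: channel mismatch");
  NumericVector gx(need_gx ? (size_t)H * W * C * N : 0);
  if (need_gx) gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  size_t Q = (size_t)Ho * Wo, K = (size_t)KH * KW * Cin;
  if (is_ws) {
    XPtr<arma::fmat> M(x);
    if (M->n_rows != Q * N || M->n_cols != K)
      stop("conv2d_bwd: workspace shape mismatch");
    conv_bwd_impl<arma::fmat>(*M, w, gy, stride, pad, H, W, C, N, KH, KW,
                              Cout, Ho, Wo, gx, gw, gb, has_bias, need_gx);
  } else if (fp32) {
    NumericVector xv(x);
    arma::fmat M(Q * N, K);
    for (int n = 0; n < N; ++n)
      im2col(xv.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
             Ho, Wo, M.memptr() + Q * (size_t)n, Q * N);
    conv_bwd_impl<arma::fmat>(M, w, gy, stride, pad, H, W, C, N, KH, KW,
                              Cout, Ho, Wo, gx, gw, gb, has_bias, need_gx);
  } else {
    NumericVector xv(x);
    arma::mat M(Q * N, K);
    for (int n = 0; n < N; ++n)
      im2col(xv.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
             Ho, Wo, M.memptr() + Q * (size_t)n, Q * N);
    conv_bwd_impl<arma::mat>(M, w, gy, stride, pad, H, W, C, N, KH, KW,
                             Cout, Ho, Wo, gx, gw, gb, has_bias, need_gx);
  }
  List out = List::create(_["gx"] = gx, _["gw"] = gw);
  if (has_bias) out["gb"] = gb;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv3_fwd(NumericVector x, NumericVector w,
                              NumericVector b) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double *yc = y.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double *wc = w.begin() + 9 * (size_t)c;
      double bc = b[c];
      for (int wo = 0; wo < W; ++wo)
        for (int ho = 0; ho < H; ++ho) {
          double acc = bc;
          for (int kj = 0; kj < 3; ++kj) {
            int wi = wo - 1 + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < 3; ++ki) {
              int hi = ho - 1 + ki;
              if (hi < 0 || hi >= H) continue;
              acc += wc[ki + 3 * kj] * xc[hi + (size_t)H * wi];
            }
          }
          yc[ho + (size_t)H * wo] = acc;
        }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv3_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size()); gw.attr("dim") = w.attr("dim");
  NumericVector gb(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double *gc = gy.begin() + (size_t)H * W * (c + (size_t)C * n);
      double *gxc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double *wc = w.begin() + 9 * (size_t)c;
      double *gwc = gw.begin() + 9 * (size_t)c;
      double gbc = 0.0;
      for (int wo = 0; wo < W; ++wo)
        for (int ho = 0; ho < H; ++ho) {
          double g = gc[ho + (size_t)H * wo];
          gbc += g;
          for (int kj = 0; kj < 3; ++kj) {
            int wi = wo - 1 + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < 3; ++ki) {
              int hi = ho - 1 + ki;
              if (hi < 0 || hi >= H) continue;
              gwc[ki + 3 * kj] += g * xc[hi + (size_t)H * wi];
              gxc[hi + (size_t)H * wi] += g * wc[ki + 3 * kj];
            }
          }
        }
      gb[c] += gbc;
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_groupnorm_fwd(NumericVector x, NumericVector gamma,
                       NumericVector beta, int groups, double eps) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (C % groups != 0) stop("group norm: %d channels not divisible by %d groups", C, groups);
  int Cg = C / groups;
  size_t M = (size_t)H * W * Cg;
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  NumericMatrix mu(groups, N), istd(groups, N);
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      const double *xg = x.begin() + (size_t)H * W * ((size_t)g * Cg + (size_t)C * n);
      double s = 0, s2 = 0;
      for (size_t i = 0; i < M; ++i) { s += xg[i]; s2 += xg[i] * xg[i]; }
      double m = s / M;
      double v = s2 / M - m * m;
      if (v < 0) v = 0;
      double is = 1.0 / std::sqrt(v + eps);
      mu(g, n) = m; istd(g, n) = is;
      double *yg = y.begin() + (size_t)H * W * ((size_t)g * Cg + (size_t)C * n);
      for (int cc = 0; cc < Cg; ++cc) {
        double ga = gamma[g * Cg + cc], be = beta[g * Cg + cc];
        const double *xs = xg + (size_t)H * W * cc;
        double *ys = yg + (size_t)H * W * cc;
        for (size_t i = 0; i < (size_t)H * W; ++i)
          ys[i] = (xs[i] - m) * is * ga + be;
      }
    }
  return List::create(_["y"] = y, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_groupnorm_bwd(NumericVector x, NumericVector gamma, NumericVector gy,
                       NumericMatrix mu, NumericMatrix istd, int groups) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int Cg = C / groups;
  size_t M = (size_t)H * W * Cg;
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  NumericVector ggamma(C), gbeta(C);
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      size_t off = (size_t)H * W * ((size_t)g * Cg + (size_t)C * n);
      const double *xg = x.begin() + off;
      const double *gg = gy.begin() + off;
      double *gxg = gx.begin() + off;
      double m = mu(g, n), is = istd(g, n);
      // accumulate sums of ghat and ghat*xhat over the group
      double sg = 0, sgx = 0;
      for (int cc = 0; cc < Cg; ++cc) {
        double ga = gamma[g * Cg + cc];
        const double *xs = xg + (size_t)H * W * cc;
        const double *gs = gg + (size_t)H * W * cc;
        double a = 0, bsum = 0, gga = 0, gbe = 0;
        for (size_t i = 0; i < (size_t)H * W; ++i) {
          double xh = (xs[i] - m) * is;
          double gh = gs[i] * ga;
          a += gh; bsum += gh * xh;
          gga += gs[i] * xh; gbe += gs[i];
        }
        sg += a; sgx += bsum;
        ggamma[g * Cg + cc] += gga;
        gbeta[g * Cg + cc] += gbe;
      }
      for (int cc = 0; cc < Cg; ++cc) {
        double ga = gamma[g * Cg + cc];
        const double *xs = xg + (size_t)H * W * cc;
        const double *gs = gg + (size_t)H * W * cc;
        double *gd = gxg + (size_t)H * W * cc;
        for (size_t i = 0; i < (size_t)H * W; ++i) {
          double xh = (xs[i] - m) * is;
          double gh = gs[i] * ga;
          gd[i] = is * (gh - sg / M - xh * sgx / M);
        }
      }
    }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// 3x3 stride-2 pad-1 max pooling with argmax cache.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int Ho = (H + 2 - 3) / 2 + 1, Wo = (W + 2 - 3) / 2 + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(y.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      double *yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int *ac = arg.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kj = 0; kj < 3; ++kj) {
            int wi = wo * 2 - 1 + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < 3; ++ki) {
              int hi = ho * 2 - 1 + ki;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; besti = hi + H * wi; }
            }
          }
          yc[ho + (size_t)Ho * wo] = best;
          ac[ho + (size_t)Ho * wo] = (int)(base + besti);
        }
    }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector argmax,
                              IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i]] += gy[i];
  return gx;
}

static inline void bil_coeff(int i, int Hin, int Hout, int &i0, int &i1,
                             double &w1) {
  double src = (i + 0.5) * (double)Hin / Hout - 0.5;
  if (src < 0) src = 0;
  if (src > Hin - 1) src = Hin - 1;
  i0 = (int)std::floor(src);
  i1 = std::min(i0 + 1, Hin - 1);
  w1 = src - i0;
}

// half-pixel-centered bilinear resize to (Ho, Wo)
// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ah(Ho), aw(Wo);
  for (int i = 0; i < Ho; ++i) bil_coeff(i, H, Ho, h0[i], h1[i], ah[i]);
  for (int j = 0; j < Wo; ++j) bil_coeff(j, W, Wo, w0[j], w1[j], aw[j]);
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double *xc = x.begin() + (size_t)H * W * p;
    double *yc = y.begin() + (size_t)Ho * Wo * p;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double a = ah[i], b = aw[j];
        double v = (1 - a) * (1 - b) * xc[h0[i] + (size_t)H * w0[j]] +
                   a * (1 - b) * xc[h1[i] + (size_t)H * w0[j]] +
                   (1 - a) * b * xc[h0[i] + (size_t)H * w1[j]] +
                   a * b * xc[h1[i] + (size_t)H * w1[j]];
        yc[i + (size_t)Ho * j] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector gy, int H, int W) {
  int Ho, Wo, C, N; get_dims4(gy, Ho, Wo, C, N);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ah(Ho), aw(Wo);
  for (int i = 0; i < Ho; ++i) bil_coeff(i, H, Ho, h0[i], h1[i], ah[i]);
  for (int j = 0; j < Wo; ++j) bil_coeff(j, W, Wo, w0[j], w1[j], aw[j]);
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double *gc = gy.begin() + (size_t)Ho * Wo * p;
    double *gxc = gx.begin() + (size_t)H * W * p;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double g = gc[i + (size_t)Ho * j];
        double a = ah[i], b = aw[j];
        gxc[h0[i] + (size_t)H * w0[j]] += (1 - a) * (1 - b) * g;
        gxc[h1[i] + (size_t)H * w0[j]] += a * (1 - b) * g;
        gxc[h0[i] + (size_t)H * w1[j]] += (1 - a) * b * g;
        gxc[h1[i] + (size_t)H * w1[j]] += a * b * g;
      }
  }
  return gx;
}

// In-place Adam step over parallel lists of parameter/gradient/moment
// arrays. The caller owns the (deep-copied) parameter arrays exclusively.
// [[Rcpp::export]]
void cpp_adam_step(List params, List grads, List m, List v, double lr,
                   double beta1, double beta2, double eps, double wd,
                   int t) {
  double bc1 = 1.0 - std::pow(beta1, t), bc2 = 1.0 - std::pow(beta2, t);
  for (int i = 0; i < params.size(); ++i) {
    NumericVector p = params[i], g = grads[i], mi = m[i], vi = v[i];
    R_xlen_t n = p.size();
    if (g.size() != n) stop("gradient %d has wrong length", i + 1);
    for (R_xlen_t j = 0; j < n; ++j) {
      double gj = g[j] + wd * p[j];
      mi[j] = beta1 * mi[j] + (1.0 - beta1) * gj;
      vi[j] = beta2 * vi[j] + (1.0 - beta2) * gj * gj;
      p[j] -= lr * (mi[j] / bc1) / (std::sqrt(vi[j] / bc2) + eps);
    }
  }
}

// Similarity-measure region partitioner (superpixel-style).
// mode 0: joint feature/spatial distance, centers searched within a 2s box
//         (falling back to the nearest center when the box holds none);
// mode 1: feature-only distance, all centers searched.
// Runs `iters` assign/update rounds with empty-region repair, then a final
// assignment so labels are consistent with the reported centers.
// [[Rcpp::export]]
List cpp_partition(NumericVector p, int H, int W, int k, double m, double s,
                   int mode, int iters) {
  std::vector<double> cv(k), ch(k), cw(k);
  int gr = (int)std::ceil(std::sqrt((double)k));
  for (int idx = 0; idx < k; ++idx) {
    int r = idx / gr, c = idx % gr;
    int hh = std::min(H - 1, (int)std::floor((r + 0.5) * H / gr));
    int ww = std::min(W - 1, (int)std::floor((c + 0.5) * W / gr));
    ch[idx] = hh; cw[idx] = ww; cv[idx] = p[hh + (size_t)H * ww];
  }
  IntegerVector labels((size_t)H * W);
  labels.attr("dim") = IntegerVector::create(H, W);
  auto dist = [&](int i, double val, double hh, double ww, int cidx) {
    double df = std::fabs(val - cv[cidx]);
    if (mode == 1) return df;
    double dh = hh - ch[cidx], dw = ww - cw[cidx];
    double ds = std::sqrt(dh * dh + dw * dw);
    double a = df / m, b = ds / s;
    (void)i;
    return std::sqrt(a * a + b * b);
  };
  auto assign = [&]() {
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double val = p[h + (size_t)H * w];
        double best = std::numeric_limits<double>::infinity();
        int bi = -1;
        for (int c = 0; c < k; ++c) {
          if (mode == 0 &&
              (std::fabs(h - ch[c]) > 2 * s || std::fabs(w - cw[c]) > 2 * s))
            continue;
          double d = dist(h + H * w, val, h, w, c);
          if (d < best) { best = d; bi = c; }
        }
        if (bi < 0) { // no center inside the search window: nearest overall
          for (int c = 0; c < k; ++c) {
            double d = dist(h + H * w, val, h, w, c);
            if (d < best) { best = d; bi = c; }
          }
        }
        labels[h + (size_t)H * w] = bi;
      }
  };
  for (int it = 0; it < iters; ++it) {
    assign();
    std::vector<double> sv(k, 0), sh(k, 0), sw(k, 0);
    std::vector<int> cnt(k, 0);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        int l = labels[h + (size_t)H * w];
        sv[l] += p[h + (size_t)H * w]; sh[l] += h; sw[l] += w; cnt[l] += 1;
      }
    for (int c = 0; c < k; ++c) {
      if (cnt[c] > 0) {
        cv[c] = sv[c] / cnt[c]; ch[c] = sh[c] / cnt[c]; cw[c] = sw[c] / cnt[c];
      } else {
        // repair: reseed at the pixel farthest (by the same distance) from
        // the empty region's current center
        double best = -1; int bh = 0, bw = 0;
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h) {
            double d = dist(h + H * w, p[h + (size_t)H * w], h, w, c);
            if (d > best) { best = d; bh = h; bw = w; }
          }
        cv[c] = p[bh + (size_t)H * bw]; ch[c] = bh; cw[c] = bw;
      }
    }
  }
  assign();
  // bounded post-pass: if the final assignment emptied a region, reseed it
  // and reassign (a center placed exactly on a pixel claims at least it,
  // except in fully degenerate ties)
  for (int pass = 0; pass < k; ++pass) {
    std::vector<int> cnt(k, 0);
    for (R_xlen_t i = 0; i < labels.size(); ++i) cnt[labels[i]] += 1;
    bool any_empty = false;
    for (int c = 0; c < k; ++c) {
      if (cnt[c] > 0) continue;
      any_empty = true;
      double best = -1; int bh = 0, bw = 0;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double d = dist(h + H * w, p[h + (size_t)H * w], h, w, c);
          if (d > best) { best = d; bh = h; bw = w; }
        }
      cv[c] = p[bh + (size_t)H * bw]; ch[c] = bh; cw[c] = bw;
    }
    if (!any_empty) break;
    assign();
  }
  NumericMatrix centers(k, 3);
  for (int c = 0; c < k; ++c) {
    centers(c, 0) = cv[c]; centers(c, 1) = ch[c]; centers(c, 2) = cw[c];
  }
  return List::create(_["labels"] = labels, _["centers"] = centers);
}
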