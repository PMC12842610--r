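// Neural-network hot kernels.
//
// Tensor layout everywhere: column-major (H, W, N, C) — spatial dims fastest,
// channels slowest.  im2col uses the transposed layout
// cols = (Ho*Wo*N) x (kh*kw*C) so that both the x reads and the cols writes
// sweep memory sequentially (the conventional kernel-major layout writes with
// a ~kh*kw*C-element stride, which thrashes every cache line on large
// feature maps).  Internally everything runs in single precision; R passes
// doubles which are converted at the boundary.  Large scratch buffers are
// reused across calls — on small containerized hosts, first-touch page
// faults on fresh mmap'd allocations cost far more than the arithmetic.

#include <RcppArmadillo.h>
#include <cstring>
#ifdef __GLIBC__
#include <malloc.h>
// Keep large allocations on the sbrk heap so they are reused warm instead of
// being mmap'd and returned to the kernel after every call.
__attribute__((constructor)) static void adamnet_malloc_tuning() {
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
}
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Function multiversioning for the bandwidth/compute-heavy elementwise loops:
// the package must compile for a generic x86-64 baseline, so the hot double
// precision kernels get AVX2/AVX-512 clones selected at load time.
#if defined(__GNUC__) && defined(__x86_64__) && !defined(__clang__)
#define ADAMNET_HOT __attribute__((target_clones("default", "avx2", "avx512f")))
#else
#define ADAMNET_HOT
#endif

// reusable scratch buffers (single-threaded R)
static std::vector<float>& scratch(int slot, size_t n) {
  static std::vector<float> bufs[16];
  if (bufs[slot].size() < n) bufs[slot].resize(n);
  return bufs[slot];
}

// single-precision GEMM from the BLAS R is linked against; used directly so
// submatrix windows can be expressed through the leading dimension.  The asm
// label avoids redeclaring the sgemm_ prototype armadillo already owns.
extern "C" void adamnet_sgemm(const char*, const char*, const int*,
                              const int*, const int*, const float*,
                              const float*, const int*, const float*,
                              const int*, const float*, float*,
                              const int*) asm("sgemm_");

static inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                         const float* a, int lda, const float* b, int ldb,
                         float beta, float* c, int ldc) {
  adamnet_sgemm(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta,
                c, &ldc);
}

ADAMNET_HOT static float* as_f(const NumericVector& x, int slot) {
  std::vector<float>& b = scratch(slot, x.size());
  const double* xp = x.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) b[i] = (float)xp[i];
  return b.data();
}

ADAMNET_HOT static NumericVector to_r(const float* x, size_t n,
                                      const IntegerVector& dim) {
  NumericVector out(n);
  double* op = out.begin();
  for (size_t i = 0; i < n; ++i) op[i] = (double)x[i];
  out.attr("dim") = dim;
  return out;
}

// ---- multiversioned double-precision loop bodies ----------------------------
// The exported kernels below cannot carry the clone attribute themselves
// (their signatures are parsed verbatim into RcppExports.cpp), so their inner
// loops live here.

ADAMNET_HOT static void mean_var_d(const double* x, size_t n,
                                   double& mu_out, double& var_out) {
  double s = 0;
  for (size_t i = 0; i < n; ++i) s += x[i];
  const double mu = s / n;
  double v = 0;
  for (size_t i = 0; i < n; ++i) { const double d = x[i] - mu; v += d * d; }
  mu_out = mu;
  var_out = v / n;
}

ADAMNET_HOT static void axpb_d(const double* x, double* y, size_t n,
                               double a, double b, bool relu) {
  if (relu) {
    for (size_t i = 0; i < n; ++i) {
      const double v = a * x[i] + b;
      y[i] = v > 0 ? v : 0.0;
    }
  } else {
    for (size_t i = 0; i < n; ++i) y[i] = a * x[i] + b;
  }
}

// mask the relu (on y), stash the masked gradient and return its plain and
// xhat-weighted sums
ADAMNET_HOT static void bn_bwd_sums_d(const double* xc, const double* yc,
                                      const double* gc, double* gxc, size_t n,
                                      double mu, double invstd, bool relu,
                                      double& s1_out, double& s2_out) {
  double s1 = 0, s2 = 0;
  for (size_t i = 0; i < n; ++i) {
    double g = gc[i];
    if (relu && yc[i] <= 0) g = 0;
    s1 += g;
    s2 += g * (xc[i] - mu) * invstd;
    gxc[i] = g;
  }
  s1_out = s1;
  s2_out = s2;
}

ADAMNET_HOT static void bn_bwd_gx_d(const double* xc, double* gxc, size_t n,
                                    double mu, double invstd, double a,
                                    double m1, double m2) {
  for (size_t i = 0; i < n; ++i) {
    const double xhat = (xc[i] - mu) * invstd;
    gxc[i] = a * (gxc[i] - m1 - xhat * m2);
  }
}

ADAMNET_HOT static void relu_d(const double* x, double* y, size_t n) {
  for (size_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
}

ADAMNET_HOT static void relu_mask_d(const double* y, const double* g,
                                    double* o, size_t n) {
  for (size_t i = 0; i < n; ++i) o[i] = y[i] > 0 ? g[i] : 0.0;
}

ADAMNET_HOT static void add_relu_d(const double* a, const double* b,
                                   double* y, size_t n) {
  for (size_t i = 0; i < n; ++i) {
    const double v = a[i] + b[i];
    y[i] = v > 0 ? v : 0.0;
  }
}

ADAMNET_HOT static void add_d(double* a, const double* b, size_t n) {
  for (size_t i = 0; i < n; ++i) a[i] += b[i];
}

// oc = gc * s and acc += gc . xc in one sweep (channel/spatial gating)
ADAMNET_HOT static double scale_dot_d(const double* xc, const double* gc,
                                      double* oc, size_t n, double s) {
  double acc = 0;
  for (size_t i = 0; i < n; ++i) {
    oc[i] = gc[i] * s;
    acc += gc[i] * xc[i];
  }
  return acc;
}

ADAMNET_HOT static void mul_d(const double* x, const double* a, double* y,
                              size_t n) {
  for (size_t i = 0; i < n; ++i) y[i] = x[i] * a[i];
}

ADAMNET_HOT static void mul_acc_d(const double* xc, const double* gc,
                                  const double* ap, double* oc, double* acc,
                                  size_t n) {
  for (size_t i = 0; i < n; ++i) {
    oc[i] = gc[i] * ap[i];
    acc[i] += gc[i] * xc[i];
  }
}

ADAMNET_HOT static void adam_d(double* vp, const double* gp, double* mp,
                               double* vv, size_t n, double beta1,
                               double beta2, double lr, double c1, double c2,
                               double eps) {
  for (size_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1.0 - beta1) * gp[i];
    vv[i] = beta2 * vv[i] + (1.0 - beta2) * gp[i] * gp[i];
    vp[i] -= lr * (mp[i] / c1) / (std::sqrt(vv[i] / c2) + eps);
  }
}

// im2col (transposed layout) over the batch range [n0, n1): x is
// (H, W, N, C); cols is (Ho*Wo*(n1-n0)) x (kh*kw*C) with row index ho
// fastest, then wo, then n, and column index dh fastest, then dw, then c.
// Every column is written as one sequential sweep; x reads are sequential
// in h.  The callers tile over n so cols stays cache-resident between the
// im2col pass and the GEMM that consumes it.
static void im2col_t(const float* xp, int H, int W, int N, int C,
                     int kh, int kw, int stride, int pad, int Ho, int Wo,
                     int n0, int n1, float* cols) {
  const size_t R = (size_t)Ho * Wo * (n1 - n0);
  const size_t planeHW = (size_t)H * W;
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        float* dst0 = cols + R * (dh + (size_t)kh * (dw + (size_t)kw * c));
        for (int n = n0; n < n1; ++n) {
          const float* xnc = xp + planeHW * (n + (size_t)N * c);
          for (int wo = 0; wo < Wo; ++wo) {
            float* d = dst0 + (size_t)Ho * (wo + (size_t)Wo * (n - n0));
            const int wi = wo * stride - pad + dw;
            if (wi < 0 || wi >= W) {
              std::memset(d, 0, (size_t)Ho * sizeof(float));
              continue;
            }
            const float* xcol = xnc + (size_t)H * wi;
            if (stride == 1) {
              const int hi0 = dh - pad;           // hi at ho = 0
              const int lo = hi0 < 0 ? -hi0 : 0;  // first valid ho
              int hi = H - hi0;                   // first invalid ho
              if (hi > Ho) hi = Ho;
              for (int ho = 0; ho < lo && ho < Ho; ++ho) d[ho] = 0.0f;
              if (hi > lo)
                std::memcpy(d + lo, xcol + hi0 + lo,
                            (size_t)(hi - lo) * sizeof(float));
              for (int ho = hi > lo ? hi : lo; ho < Ho; ++ho) d[ho] = 0.0f;
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride - pad + dh;
                d[ho] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0f;
              }
            }
          }
        }
      }
}

// col2im: adjoint of im2col_t over [n0, n1) (scatter-add); x pre-zeroed.
static void col2im_t(const float* cols, int H, int W, int N, int C,
                     int kh, int kw, int stride, int pad, int Ho, int Wo,
                     int n0, int n1, float* xp) {
  const size_t R = (size_t)Ho * Wo * (n1 - n0);
  const size_t planeHW = (size_t)H * W;
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        const float* src0 = cols + R * (dh + (size_t)kh * (dw + (size_t)kw * c));
        for (int n = n0; n < n1; ++n) {
          float* xnc = xp + planeHW * (n + (size_t)N * c);
          for (int wo = 0; wo < Wo; ++wo) {
            const float* s = src0 + (size_t)Ho * (wo + (size_t)Wo * (n - n0));
            const int wi = wo * stride - pad + dw;
            if (wi < 0 || wi >= W) continue;
            float* xcol = xnc + (size_t)H * wi;
            if (stride == 1) {
              const int hi0 = dh - pad;
              const int lo = hi0 < 0 ? -hi0 : 0;
              int hi = H - hi0;
              if (hi > Ho) hi = Ho;
              for (int ho = lo; ho < hi; ++ho) xcol[hi0 + ho] += s[ho];
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride - pad + dh;
                if (hi >= 0 && hi < H) xcol[hi] += s[ho];
              }
            }
          }
        }
      }
}

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// batch-chunk size keeping a (rows x K) cols block around 2 MB
static inline int chunk_n(size_t rows_per_n, size_t K, int N) {
  const size_t target = (size_t)1 << 19;          // floats
  size_t rows = target / (K > 0 ? K : 1);
  int cn = (int)(rows / (rows_per_n > 0 ? rows_per_n : 1));
  if (cn < 1) cn = 1;
  if (cn > N) cn = N;
  return cn;
}

// ---- fast path for 3x3 stride-1 same-pad convolutions -----------------------
//
// im2col inflates memory traffic nine-fold, which makes the narrow-channel
// convolutions of the small backbones memory-bound.  Instead, embed the
// chunk in a zero-padded (Hp, Wp, cn, C) buffer and express the convolution
// as nine shifted rank-Cin GEMM updates
//     ypad[r] += xpad[r + s] * W[dh, dw],   s = (dh - 1) + Hp (dw - 1),
// using the leading-dimension argument of sgemm for the row offsets.  The
// zero borders absorb every shift that crosses an image, column, or channel
// boundary, and with small chunks all buffers stay cache-resident.

// embed the [n0, n1) batch slice of x (H, W, N, C) into a zero-padded
// (Hp, Wp, n1-n0, C) buffer with border p
static void pad_embed(const float* xp, int H, int W, int N, int C, int p,
                      int n0, int n1, float* xpad) {
  const int Hp = H + 2 * p, Wp = W + 2 * p, cn = n1 - n0;
  std::memset(xpad, 0, (size_t)Hp * Wp * cn * C * sizeof(float));
  for (int c = 0; c < C; ++c)
    for (int n = n0; n < n1; ++n) {
      const float* src = xp + (size_t)H * W * (n + (size_t)N * c);
      float* dst = xpad + (size_t)Hp * Wp * ((n - n0) + (size_t)cn * c)
                 + (size_t)Hp * p + p;
      for (int w = 0; w < W; ++w)
        std::memcpy(dst + (size_t)Hp * w, src + (size_t)H * w,
                    (size_t)H * sizeof(float));
    }
}

// copy the interior of ypad back into the [n0, n1) slice of y (H, W, N, C),
// optionally adding a per-channel bias
static void pad_extract(const float* ypad, int H, int W, int N, int C, int p,
                        int n0, int n1, const float* bias, float* yp) {
  const int Hp = H + 2 * p, Wp = W + 2 * p, cn = n1 - n0;
  for (int c = 0; c < C; ++c)
    for (int n = n0; n < n1; ++n) {
      const float* src = ypad + (size_t)Hp * Wp * ((n - n0) + (size_t)cn * c)
                       + (size_t)Hp * p + p;
      float* dst = yp + (size_t)H * W * (n + (size_t)N * c);
      for (int w = 0; w < W; ++w) {
        const float* s = src + (size_t)Hp * w;
        float* d = dst + (size_t)H * w;
        if (bias) {
          const float bc = bias[c];
          for (int h = 0; h < H; ++h) d[h] = s[h] + bc;
        } else {
          std::memcpy(d, s, (size_t)H * sizeof(float));
        }
      }
    }
}

// batch-chunk size keeping all padded buffers around 6 MB together: large
// enough for efficient tall GEMM panels, small enough to stay in LLC
static inline int chunk3_n(int HpWp, int Csum, int N) {
  const size_t target = (size_t)3 << 19;  // floats
  int cn = (int)(target / ((size_t)HpWp * (Csum > 0 ? Csum : 1)));
  if (cn < 1) cn = 1;
  if (cn > N) cn = N;
  return cn;
}

// Direct vectorized microkernels for the 3x3 stride-1 path.  The GEMM
// panels of the shifted-GEMM formulation are too skinny (m large, n = k =
// channel count) for BLAS to run near peak, so on x86 the nine-tap sums are
// computed directly: accumulators run over a vector of consecutive h
// positions and a block of four output channels, with the zero-padded
// columns making every load branch-free.  Compiled once for AVX2+FMA and
// once for AVX-512 via the target attribute and selected at runtime, with
// the shifted-GEMM path as the portable fallback.
static int mk_level() {
  static int lvl = -1;
  if (lvl < 0) {
    lvl = 0;
#if defined(__GNUC__) && defined(__x86_64__)
    if (__builtin_cpu_supports("avx2") && __builtin_cpu_supports("fma"))
      lvl = 1;
    if (__builtin_cpu_supports("avx512f")) lvl = 2;
#endif
  }
  return lvl;
}

#if defined(__GNUC__) && defined(__x86_64__)
// CBF output channels are produced per pass so each trio of shifted input
// loads feeds 3*CBF FMAs; accumulator arrays are fully unrolled into
// registers (4 ymm blocks for AVX2, 8 zmm blocks for AVX-512).
#define DEF_CONV3_MK(SUFF, VL, TGT, CBF)                                      \
  __attribute__((target(TGT))) static void conv3_mk_fwd_##SUFF(               \
      const float* xpad, const float* wf, const float* bf, int H, int W,      \
      int N, int Cin, int Cout, int n0, int n1, float* yf) {                  \
    typedef float vf __attribute__((vector_size(VL * 4)));                    \
    const int Hp = H + 2, Wp = W + 2, cnc = n1 - n0;                          \
    const size_t T0 = (size_t)Hp * Wp * cnc;                                  \
    const size_t planeY = (size_t)H * W * N;                                  \
    const size_t wco = 9 * (size_t)Cin;                                       \
    for (int nl = 0; nl < cnc; ++nl)                                          \
      for (int w0 = 0; w0 < W; ++w0) {                                        \
        const float* xcol = xpad + (size_t)Hp * (w0 + (size_t)Wp * nl);       \
        float* ycol = yf + (size_t)H * (w0 + (size_t)W * (n0 + nl));          \
        int co0 = 0;                                                          \
        for (; co0 + CBF <= Cout; co0 += CBF)                                 \
          for (int h = 0; h < H; h += VL) {                                   \
            if (h + VL > H) h = H - VL; /* overlap tail: values identical */  \
            vf acc[CBF];                                                      \
            _Pragma("GCC unroll 8")                                           \
            for (int j = 0; j < CBF; ++j)                                     \
              acc[j] = (vf){} + (bf ? bf[co0 + j] : 0.f);                     \
            for (int ci = 0; ci < Cin; ++ci) {                                \
              const float* xc = xcol + T0 * ci + h;                           \
              const float* wl = wf + 9 * ci + wco * co0;                      \
              _Pragma("GCC unroll 3")                                         \
              for (int dw = 0; dw < 3; ++dw) {                                \
                vf v0, v1, v2;                                                \
                __builtin_memcpy(&v0, xc + (size_t)Hp * dw, sizeof v0);       \
                __builtin_memcpy(&v1, xc + (size_t)Hp * dw + 1, sizeof v1);   \
                __builtin_memcpy(&v2, xc + (size_t)Hp * dw + 2, sizeof v2);   \
                _Pragma("GCC unroll 8")                                       \
                for (int j = 0; j < CBF; ++j) {                               \
                  const float* t = wl + 3 * dw + wco * j;                     \
                  acc[j] += v0 * t[0] + v1 * t[1] + v2 * t[2];                \
                }                                                             \
              }                                                               \
            }                                                                 \
            _Pragma("GCC unroll 8")                                           \
            for (int j = 0; j < CBF; ++j)                                     \
              __builtin_memcpy(ycol + planeY * (co0 + j) + h, &acc[j],        \
                               sizeof acc[j]);                                \
          }                                                                   \
        for (; co0 < Cout; ++co0)                                             \
          for (int h = 0; h < H; h += VL) {                                   \
            if (h + VL > H) h = H - VL;                                       \
            vf a0 = (vf){} + (bf ? bf[co0] : 0.f);                            \
            for (int ci = 0; ci < Cin; ++ci) {                                \
              const float* xc = xcol + T0 * ci + h;                           \
              const float* t0 = wf + 9 * ci + wco * co0;                      \
              for (int dw = 0; dw < 3; ++dw) {                                \
                vf v0, v1, v2;                                                \
                __builtin_memcpy(&v0, xc + (size_t)Hp * dw, sizeof v0);       \
                __builtin_memcpy(&v1, xc + (size_t)Hp * dw + 1, sizeof v1);   \
                __builtin_memcpy(&v2, xc + (size_t)Hp * dw + 2, sizeof v2);   \
                a0 += v0 * t0[3 * dw] + v1 * t0[3 * dw + 1] +                 \
                      v2 * t0[3 * dw + 2];                                    \
              }                                                               \
            }                                                                 \
            __builtin_memcpy(ycol + planeY * co0 + h, &a0, sizeof a0);        \
          }                                                                   \
      }                                                                       \
  }                                                                           \
  __attribute__((target(TGT))) static void conv3_mk_gw_##SUFF(                \
      const float* xpad, const float* gyf, int H, int W, int N, int Cin,      \
      int Cout, int n0, int n1, int co_from, float* gwbuf) {                  \
    typedef float vf __attribute__((vector_size(VL * 4)));                    \
    const int Hp = H + 2, Wp = W + 2, cnc = n1 - n0;                          \
    const size_t T0 = (size_t)Hp * Wp * cnc;                                  \
    const size_t planeG = (size_t)H * W * N;                                  \
    const int HV = H - H % VL;                                                \
    for (int co = co_from; co < Cout; ++co)                                   \
      for (int ci = 0; ci < Cin; ++ci) {                                      \
        vf a00 = (vf){}, a10 = (vf){}, a20 = (vf){};                          \
        vf a01 = (vf){}, a11 = (vf){}, a21 = (vf){};                          \
        vf a02 = (vf){}, a12 = (vf){}, a22 = (vf){};                          \
        float s[9] = {0};                                                     \
        for (int nl = 0; nl < cnc; ++nl)                                      \
          for (int w0 = 0; w0 < W; ++w0) {                                    \
            const float* xc =                                                 \
                xpad + T0 * ci + (size_t)Hp * (w0 + (size_t)Wp * nl);         \
            const float* gc = gyf + planeG * co +                             \
                              (size_t)H * (w0 + (size_t)W * (n0 + nl));       \
            for (int h = 0; h < HV; h += VL) {                                \
              vf g, x0, x1, x2;                                               \
              __builtin_memcpy(&g, gc + h, sizeof g);                         \
              const float* c0 = xc + h;                                       \
              __builtin_memcpy(&x0, c0, sizeof x0);                           \
              __builtin_memcpy(&x1, c0 + 1, sizeof x1);                       \
              __builtin_memcpy(&x2, c0 + 2, sizeof x2);                       \
              a00 += g * x0; a10 += g * x1; a20 += g * x2;                    \
              const float* c1 = c0 + Hp;                                      \
              __builtin_memcpy(&x0, c1, sizeof x0);                           \
              __builtin_memcpy(&x1, c1 + 1, sizeof x1);                       \
              __builtin_memcpy(&x2, c1 + 2, sizeof x2);                       \
              a01 += g * x0; a11 += g * x1; a21 += g * x2;                    \
              const float* c2 = c1 + Hp;                                      \
              __builtin_memcpy(&x0, c2, sizeof x0);                           \
              __builtin_memcpy(&x1, c2 + 1, sizeof x1);                       \
              __builtin_memcpy(&x2, c2 + 2, sizeof x2);                       \
              a02 += g * x0; a12 += g * x1; a22 += g * x2;                    \
            }                                                                 \
            for (int h = HV; h < H; ++h) {                                    \
              const float g = gc[h];                                          \
              for (int dw = 0; dw < 3; ++dw)                                  \
                for (int dh = 0; dh < 3; ++dh)                                \
                  s[dh + 3 * dw] += g * xc[(size_t)Hp * dw + h + dh];         \
            }                                                                 \
          }                                                                   \
        const vf* av[9] = {&a00, &a01, &a02, &a10, &a11, &a12,                \
                           &a20, &a21, &a22};                                 \
        for (int tap = 0; tap < 9; ++tap) {                                   \
          /* av is indexed (dh, dw); tap order in gwbuf is dh + 3 dw */       \
          const vf& a = *av[3 * (tap % 3) + tap / 3];                         \
          float acc = s[tap];                                                 \
          for (int l = 0; l < VL; ++l) acc += a[l];                           \
          gwbuf[(size_t)tap * Cin * Cout + ci + (size_t)Cin * co] += acc;     \
        }                                                                     \
      }                                                                       \
  }

DEF_CONV3_MK(v8, 8, "avx2,fma", 4)
DEF_CONV3_MK(v16, 16, "avx512f", 8)
#undef DEF_CONV3_MK

// weight-gradient kernel over pairs of output channels: the nine shifted
// input loads are shared by both channels, doubling the FMA density of
// conv3_mk_gw_v16; an odd final channel falls back to the single-co kernel.
__attribute__((target("avx512f"))) static void conv3_mk_gw2_v16(
    const float* xpad, const float* gyf, int H, int W, int N, int Cin,
    int Cout, int n0, int n1, float* gwbuf) {
  typedef float vf __attribute__((vector_size(64)));
  const int VL = 16;
  const int Hp = H + 2, Wp = W + 2, cnc = n1 - n0;
  const size_t T0 = (size_t)Hp * Wp * cnc;
  const size_t planeG = (size_t)H * W * N;
  const int HV = H - H % VL;
  for (int co = 0; co + 2 <= Cout; co += 2)
    for (int ci = 0; ci < Cin; ++ci) {
      vf A0[9], A1[9];
      _Pragma("GCC unroll 9")
      for (int t = 0; t < 9; ++t) { A0[t] = (vf){}; A1[t] = (vf){}; }
      float s0[9] = {0}, s1[9] = {0};
      for (int nl = 0; nl < cnc; ++nl)
        for (int w0 = 0; w0 < W; ++w0) {
          const float* xc =
              xpad + T0 * ci + (size_t)Hp * (w0 + (size_t)Wp * nl);
          const float* gc0 = gyf + planeG * co +
                             (size_t)H * (w0 + (size_t)W * (n0 + nl));
          const float* gc1 = gc0 + planeG;
          for (int h = 0; h < HV; h += VL) {
            vf g0, g1;
            __builtin_memcpy(&g0, gc0 + h, sizeof g0);
            __builtin_memcpy(&g1, gc1 + h, sizeof g1);
            _Pragma("GCC unroll 3")
            for (int dw = 0; dw < 3; ++dw) {
              _Pragma("GCC unroll 3")
              for (int dh = 0; dh < 3; ++dh) {
                vf x;
                __builtin_memcpy(&x, xc + (size_t)Hp * dw + h + dh, sizeof x);
                A0[dh + 3 * dw] += g0 * x;
                A1[dh + 3 * dw] += g1 * x;
              }
            }
          }
          for (int h = HV; h < H; ++h) {
            const float g0s = gc0[h], g1s = gc1[h];
            for (int dw = 0; dw < 3; ++dw)
              for (int dh = 0; dh < 3; ++dh) {
                const float xv = xc[(size_t)Hp * dw + h + dh];
                s0[dh + 3 * dw] += g0s * xv;
                s1[dh + 3 * dw] += g1s * xv;
              }
          }
        }
      for (int tap = 0; tap < 9; ++tap) {
        float acc0 = s0[tap], acc1 = s1[tap];
        for (int l = 0; l < VL; ++l) { acc0 += A0[tap][l]; acc1 += A1[tap][l]; }
        float* gwt = gwbuf + (size_t)tap * Cin * Cout + ci;
        gwt[(size_t)Cin * co] += acc0;
        gwt[(size_t)Cin * (co + 1)] += acc1;
      }
    }
}
#endif  // __GNUC__ && __x86_64__

static void conv3_forward(const float* xf, const float* wf, const float* bf,
                          int H, int W, int N, int Cin, int Cout, float* yf) {
  const int Hp = H + 2, Wp = W + 2;
  const int cn = chunk3_n(Hp * Wp, Cin + Cout, N);
  float* xpad = scratch(8, (size_t)Hp * Wp * cn * Cin).data();
  float* ypad = scratch(9, (size_t)Hp * Wp * cn * Cout).data();
  float* ws = scratch(12, (size_t)Cin * Cout).data();
  const int lvl = mk_level();
  for (int n0 = 0; n0 < N; n0 += cn) {
    const int n1 = std::min(n0 + cn, N);
    const int T0 = Hp * Wp * (n1 - n0);
    pad_embed(xf, H, W, N, Cin, 1, n0, n1, xpad);
#if defined(__GNUC__) && defined(__x86_64__)
    if (lvl >= 2 && H >= 16) {
      conv3_mk_fwd_v16(xpad, wf, bf, H, W, N, Cin, Cout, n0, n1, yf);
      continue;
    }
    if (lvl >= 1 && H >= 8) {
      conv3_mk_fwd_v8(xpad, wf, bf, H, W, N, Cin, Cout, n0, n1, yf);
      continue;
    }
#endif
    (void)lvl;
    std::memset(ypad, 0, (size_t)T0 * Cout * sizeof(float));
    for (int dw = 0; dw < 3; ++dw)
      for (int dh = 0; dh < 3; ++dh) {
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            ws[ci + (size_t)Cin * co] =
                wf[dh + 3 * (dw + 3 * (ci + (size_t)Cin * co))];
        const int s = (dh - 1) + Hp * (dw - 1);
        const int a0 = s > 0 ? s : 0, c0 = s > 0 ? 0 : -s;
        const int L = T0 - (s > 0 ? s : -s);
        sgemm('N', 'N', L, Cout, Cin, 1.0f, xpad + a0, T0, ws, Cin, 1.0f,
              ypad + c0, T0);
      }
    pad_extract(ypad, H, W, N, Cout, 1, n0, n1, bf, yf);
  }
}

static void conv3_backward(const float* xf, const float* wf, const float* gyf,
                           int H, int W, int N, int Cin, int Cout,
                           bool need_gx, float* gxf, float* gw) {
  const int Hp = H + 2, Wp = W + 2;
  const int cn = chunk3_n(Hp * Wp, 2 * Cin + Cout, N);
  float* xpad = scratch(8, (size_t)Hp * Wp * cn * Cin).data();
  float* gypad = scratch(9, (size_t)Hp * Wp * cn * Cout).data();
  float* gxpad = scratch(10, (size_t)Hp * Wp * cn * Cin).data();
  float* gwbuf = scratch(11, (size_t)9 * Cin * Cout).data();
  float* ws = scratch(12, (size_t)Cin * Cout).data();
  std::memset(gwbuf, 0, (size_t)9 * Cin * Cout * sizeof(float));
  const int lvl = mk_level();
#if defined(__GNUC__) && defined(__x86_64__)
  const int mkv = (lvl >= 2 && H >= 16) ? 16 : (lvl >= 1 && H >= 8) ? 8 : 0;
  float* wrot = scratch(14, (size_t)9 * Cin * Cout).data();
  if (mkv && need_gx) {
    // dX is the convolution of gY with the flipped, transposed kernel
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        for (int aw = 0; aw < 3; ++aw)
          for (int ah = 0; ah < 3; ++ah)
            wrot[ah + 3 * (aw + 3 * (co + (size_t)Cout * ci))] =
                wf[(2 - ah) + 3 * ((2 - aw) + 3 * (ci + (size_t)Cin * co))];
  }
#endif
  for (int n0 = 0; n0 < N; n0 += cn) {
    const int n1 = std::min(n0 + cn, N);
    const int T0 = Hp * Wp * (n1 - n0);
    pad_embed(xf, H, W, N, Cin, 1, n0, n1, xpad);
#if defined(__GNUC__) && defined(__x86_64__)
    if (mkv) {
      if (mkv == 16) {
        conv3_mk_gw2_v16(xpad, gyf, H, W, N, Cin, Cout, n0, n1, gwbuf);
        if (Cout % 2)
          conv3_mk_gw_v16(xpad, gyf, H, W, N, Cin, Cout, n0, n1, Cout - 1,
                          gwbuf);
      } else {
        conv3_mk_gw_v8(xpad, gyf, H, W, N, Cin, Cout, n0, n1, 0, gwbuf);
      }
      if (need_gx) {
        pad_embed(gyf, H, W, N, Cout, 1, n0, n1, gypad);
        if (mkv == 16)
          conv3_mk_fwd_v16(gypad, wrot, nullptr, H, W, N, Cout, Cin, n0, n1,
                           gxf);
        else
          conv3_mk_fwd_v8(gypad, wrot, nullptr, H, W, N, Cout, Cin, n0, n1,
                          gxf);
      }
      continue;
    }
#endif
    (void)lvl;
    pad_embed(gyf, H, W, N, Cout, 1, n0, n1, gypad);
    if (need_gx) std::memset(gxpad, 0, (size_t)T0 * Cin * sizeof(float));
    for (int dw = 0; dw < 3; ++dw)
      for (int dh = 0; dh < 3; ++dh) {
        // both products pair xpad[r] (resp. gxpad[r]) with gypad[r + s]
        const int s = (1 - dh) + Hp * (1 - dw);
        const int a0 = s < 0 ? -s : 0, g0 = s < 0 ? 0 : s;
        const int L = T0 - (s > 0 ? s : -s);
        // dW[dh,dw] += xpad^T gypad (accumulated across chunks)
        sgemm('T', 'N', Cin, Cout, L, 1.0f, xpad + a0, T0, gypad + g0, T0,
              1.0f, gwbuf + (size_t)(dh + 3 * dw) * Cin * Cout, Cin);
        if (need_gx) {
          for (int co = 0; co < Cout; ++co)
            for (int ci = 0; ci < Cin; ++ci)
              ws[ci + (size_t)Cin * co] =
                  wf[dh + 3 * (dw + 3 * (ci + (size_t)Cin * co))];
          // dX[r] += gY[r + s] W[dh,dw]^T
          sgemm('N', 'T', L, Cin, Cout, 1.0f, gypad + g0, T0, ws, Cin, 1.0f,
                gxpad + a0, T0);
        }
      }
    if (need_gx) pad_extract(gxpad, H, W, N, Cin, 1, n0, n1, nullptr, gxf);
  }
  // gwbuf is (Cin, Cout) per (dh, dw); gw is (3, 3, Cin, Cout)
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dw = 0; dw < 3; ++dw)
        for (int dh = 0; dh < 3; ++dh)
          gw[dh + 3 * (dw + 3 * (ci + (size_t)Cin * co))] =
              gwbuf[(size_t)(dh + 3 * dw) * Cin * Cout + ci +
                    (size_t)Cin * co];
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const size_t R = (size_t)Ho * Wo * N, K = (size_t)kh * kw * Cin;
  float* xf = as_f(x, 0);
  float* wf = as_f(w, 1);
  if (stride == 1 && kh == 3 && kw == 3 && pad == 1) {
    float* yf = scratch(3, R * Cout).data();
    conv3_forward(xf, wf, as_f(b, 4), H, W, N, C, Cout, yf);
    return to_r(yf, R * Cout, IntegerVector::create(Ho, Wo, N, Cout));
  }
  if (stride == 1 && kh == 1 && kw == 1 && pad == 0) {
    // 1x1 convolution is a plain (H*W*N, Cin) x (Cin, Cout) GEMM
    float* yf = scratch(3, R * Cout).data();
    sgemm('N', 'N', (int)R, Cout, Cin, 1.0f, xf, (int)R, wf, Cin, 0.0f,
          yf, (int)R);
    const float* bf = as_f(b, 4);
    for (int co = 0; co < Cout; ++co) {
      float* yc = yf + R * co;
      const float bc = bf[co];
      for (size_t i = 0; i < R; ++i) yc[i] += bc;
    }
    return to_r(yf, R * Cout, IntegerVector::create(Ho, Wo, N, Cout));
  }
  const size_t rpn = (size_t)Ho * Wo;
  const int cn = chunk_n(rpn, K, N);
  float* cf = scratch(2, rpn * cn * K).data();
  arma::fmat Wm(wf, K, Cout, false, true);
  float* yf = scratch(3, R * Cout).data();
  arma::fmat Y(yf, R, Cout, false, true);
  for (int n0 = 0; n0 < N; n0 += cn) {
    const int n1 = std::min(n0 + cn, N);
    const size_t rc = rpn * (n1 - n0);
    im2col_t(xf, H, W, N, C, kh, kw, stride, pad, Ho, Wo, n0, n1, cf);
    arma::fmat cols(cf, rc, K, false, true);
    Y.rows(rpn * n0, rpn * n0 + rc - 1) = cols * Wm;
  }
  arma::fvec bf(as_f(b, 1 + 3), Cout, false, true);  // slot 4
  Y.each_row() += bf.t();
  return to_r(yf, R * Cout, IntegerVector::create(Ho, Wo, N, Cout));
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         int stride, int pad, bool need_gx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const size_t R = (size_t)Ho * Wo * N, K = (size_t)kh * kw * Cin;
  float* xf = as_f(x, 0);
  float* wf = as_f(w, 1);
  float* gf = as_f(gy, 5);
  if (stride == 1 && ((kh == 3 && kw == 3 && pad == 1) ||
                      (kh == 1 && kw == 1 && pad == 0))) {
    float* gxf2 = scratch(7, (size_t)H * W * N * C).data();
    float* gwf = scratch(13, K * Cout).data();
    if (kh == 3) {
      conv3_backward(xf, wf, gf, H, W, N, C, Cout, need_gx, gxf2, gwf);
    } else if ((size_t)Cin * Cout <= 1024) {
      // narrow 1x1: plain loops beat the degenerate GEMM panel shapes
      for (int ci = 0; ci < Cin; ++ci)
        for (int co = 0; co < Cout; ++co) {
          const float* xc = xf + R * ci;
          const float* gc = gf + R * co;
          float acc[8] = {0};
          size_t i = 0;
          for (; i + 8 <= R; i += 8)
            for (int l = 0; l < 8; ++l) acc[l] += xc[i + l] * gc[i + l];
          float t = 0;
          for (; i < R; ++i) t += xc[i] * gc[i];
          for (int l = 0; l < 8; ++l) t += acc[l];
          gwf[ci + (size_t)Cin * co] = t;
        }
      if (need_gx)
        for (int ci = 0; ci < Cin; ++ci) {
          float* gxc = gxf2 + R * ci;
          const float w0 = wf[ci];
          for (size_t i = 0; i < R; ++i) gxc[i] = gf[i] * w0;
          for (int co = 1; co < Cout; ++co) {
            const float* gc = gf + R * co;
            const float wv = wf[ci + (size_t)Cin * co];
            for (size_t i = 0; i < R; ++i) gxc[i] += gc[i] * wv;
          }
        }
    } else {
      sgemm('T', 'N', (int)K, Cout, (int)R, 1.0f, xf, (int)R, gf, (int)R,
            0.0f, gwf, (int)K);
      if (need_gx)
        sgemm('N', 'T', (int)R, Cin, Cout, 1.0f, gf, (int)R, wf, Cin, 0.0f,
              gxf2, (int)R);
    }
    NumericVector gb(Cout);
    for (int co = 0; co < Cout; ++co) {
      const float* gc = gf + R * co;
      double acc = 0;
      for (size_t i = 0; i < R; ++i) acc += gc[i];
      gb[co] = acc;
    }
    return List::create(
        _["gx"] = need_gx ? (SEXP)to_r(gxf2, (size_t)H * W * N * C, xd)
                          : R_NilValue,
        _["gw"] = to_r(gwf, K * Cout, wd),
        _["gb"] = gb);
  }
  const size_t rpn = (size_t)Ho * Wo;
  const int cn = chunk_n(rpn, K, N);
  float* cf = scratch(2, rpn * cn * K).data();
  float* gcf = scratch(6, rpn * cn * K).data();
  arma::fmat G(gf, R, Cout, false, true);
  arma::fmat Wm(wf, K, Cout, false, true);
  arma::fmat gW(K, Cout, arma::fill::zeros);
  arma::frowvec gB = arma::sum(G, 0);
  float* gxf = scratch(7, (size_t)H * W * N * C).data();
  if (need_gx) std::memset(gxf, 0, (size_t)H * W * N * C * sizeof(float));
  for (int n0 = 0; n0 < N; n0 += cn) {
    const int n1 = std::min(n0 + cn, N);
    const size_t rc = rpn * (n1 - n0);
    im2col_t(xf, H, W, N, C, kh, kw, stride, pad, Ho, Wo, n0, n1, cf);
    arma::fmat cols(cf, rc, K, false, true);
    arma::fmat Gc = G.rows(rpn * n0, rpn * n0 + rc - 1);
    gW += cols.t() * Gc;
    if (need_gx) {
      arma::fmat gcols(gcf, rc, K, false, true);
      gcols = Gc * Wm.t();
      col2im_t(gcf, H, W, N, C, kh, kw, stride, pad, Ho, Wo, n0, n1, gxf);
    }
  }
  arma::fvec gWv(gW.memptr(), gW.n_elem, false, true);
  return List::create(
      _["gx"] = need_gx ? (SEXP)to_r(gxf, (size_t)H * W * N * C, xd)
                        : R_NilValue,
      _["gw"] = to_r(gWv.memptr(), gWv.n_elem, wd),
      _["gb"] = NumericVector(gB.begin(), gB.end()));
}

// Transposed convolution, kernel k, stride k (non-overlapping upsampling).
// w is (kh, kw, Cout, Cin); x is (H, W, N, Cin); output (H*s, W*s, N, Cout).
// [[Rcpp::export]]
NumericVector cpp_convT2d_forward(NumericVector x, NumericVector w,
                                  NumericVector b, int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], N = xd[2], Cin = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[2];
  if (wd[3] != Cin) stop("convT2d: channel mismatch");
  int Ho = H * stride, Wo = W * stride;
  const size_t R = (size_t)H * W * N, K = (size_t)kh * kw * Cout;
  float* xf = as_f(x, 0);
  float* wf = as_f(w, 1);
  arma::fmat X(xf, R, Cin, false, true);
  arma::fmat Wt(wf, K, Cin, false, true);
  const size_t rpn = (size_t)H * W;
  const int cn = chunk_n(rpn, K, N);
  float* cf = scratch(2, rpn * cn * K).data();
  const size_t ylen = (size_t)Ho * Wo * N * Cout;
  float* yf = scratch(3, ylen).data();
  std::memset(yf, 0, ylen * sizeof(float));
  for (int n0 = 0; n0 < N; n0 += cn) {
    const int n1 = std::min(n0 + cn, N);
    const size_t rc = rpn * (n1 - n0);
    arma::fmat cols(cf, rc, K, false, true);
    cols = X.rows(rpn * n0, rpn * n0 + rc - 1) * Wt.t();
    col2im_t(cf, Ho, Wo, N, Cout, kh, kw, stride, 0, H, W, n0, n1, yf);
  }
  arma::fmat Y(yf, (size_t)Ho * Wo * N, Cout, false, true);
  arma::fvec bf(as_f(b, 4), Cout, false, true);
  Y.each_row() += bf.t();
  return to_r(yf, ylen, IntegerVector::create(Ho, Wo, N, Cout));
}

// [[Rcpp::export]]
List cpp_convT2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                          int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], N = xd[2], Cin = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[2];
  int Ho = H * stride, Wo = W * stride;
  const size_t R = (size_t)H * W * N, K = (size_t)kh * kw * Cout;
  float* xf = as_f(x, 0);
  float* wf = as_f(w, 1);
  float* gf = as_f(gy, 5);
  arma::fmat X(xf, R, Cin, false, true);
  arma::fmat Wt(wf, K, Cin, false, true);
  const size_t rpn = (size_t)H * W;
  const int cn = chunk_n(rpn, K, N);
  float* dcf = scratch(2, rpn * cn * K).data();
  arma::fmat gW(K, Cin, arma::fill::zeros);
  arma::fmat G(gf, (size_t)Ho * Wo * N, Cout, false, true);
  arma::frowvec gB = arma::sum(G, 0);
  float* gxf = scratch(7, R * Cin).data();
  arma::fmat gX(gxf, R, Cin, false, true);
  for (int n0 = 0; n0 < N; n0 += cn) {
    const int n1 = std::min(n0 + cn, N);
    const size_t rc = rpn * (n1 - n0);
    im2col_t(gf, Ho, Wo, N, Cout, kh, kw, stride, 0, H, W, n0, n1, dcf);
    arma::fmat dcols(dcf, rc, K, false, true);
    gW += dcols.t() * X.rows(rpn * n0, rpn * n0 + rc - 1);
    gX.rows(rpn * n0, rpn * n0 + rc - 1) = dcols * Wt;
  }
  arma::fvec gWv(gW.memptr(), gW.n_elem, false, true);
  return List::create(
      _["gx"] = to_r(gxf, R * Cin, xd),
      _["gw"] = to_r(gWv.memptr(), gWv.n_elem, wd),
      _["gb"] = NumericVector(gB.begin(), gB.end()));
}

// Max pooling; returns pooled values and 1-based argmax linear indices into x.
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y((R_xlen_t)Ho * Wo * N * C);
  IntegerVector idx((R_xlen_t)Ho * Wo * N * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* xs = xp + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
      const R_xlen_t base = (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY; R_xlen_t bi = -1;
          for (int dw = 0; dw < k; ++dw) {
            int wi = wo * stride - pad + dw;
            if (wi < 0 || wi >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              int hi = ho * stride - pad + dh;
              if (hi < 0 || hi >= H) continue;
              double v = xs[hi + (R_xlen_t)H * wi];
              if (v > best) { best = v; bi = hi + (R_xlen_t)H * wi; }
            }
          }
          // (ho, wo, n, c) destination, column-major
          R_xlen_t dst = ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (n + (R_xlen_t)N * c));
          y[dst] = best;
          idx[dst] = (int)(base + bi) + 1;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(IntegerVector idx, NumericVector gy,
                                   IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// Batch normalisation over (H, W, N, C) with channel reductions; optionally
// fuses the following ReLU.  Returns y plus the per-channel statistics the
// backward pass needs; running-statistic updates happen in R.
// [[Rcpp::export]]
List cpp_bn2d_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                      NumericVector mean_in, NumericVector var_in,
                      bool use_batch, double eps, bool relu) {
  IntegerVector xd = x.attr("dim");
  const size_t M = (size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  const double* xp = x.begin();
  std::vector<double> mu(C), invstd(C), var(C);
  if (use_batch) {
    for (int c = 0; c < C; ++c) mean_var_d(xp + M * c, M, mu[c], var[c]);
  } else {
    for (int c = 0; c < C; ++c) { mu[c] = mean_in[c]; var[c] = var_in[c]; }
  }
  NumericVector y(x.size());
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    invstd[c] = 1.0 / std::sqrt(var[c] + eps);
    const double a = gamma[c] * invstd[c];
    const double b = beta[c] - a * mu[c];
    axpb_d(xp + M * c, yp + M * c, M, a, b, relu);
  }
  y.attr("dim") = xd;
  return List::create(_["y"] = y,
                      _["mu"] = NumericVector(mu.begin(), mu.end()),
                      _["var"] = NumericVector(var.begin(), var.end()),
                      _["invstd"] = NumericVector(invstd.begin(), invstd.end()));
}

// [[Rcpp::export]]
List cpp_bn2d_backward(NumericVector x, NumericVector y, NumericVector gy,
                       NumericVector gamma, NumericVector mu,
                       NumericVector invstd, bool use_batch, bool relu) {
  IntegerVector xd = x.attr("dim");
  const size_t M = (size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  const double* xp = x.begin();
  const double* yp = y.begin();
  const double* gp = gy.begin();
  NumericVector gx(x.size()), ggamma(C), gbeta(C);
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + M * c;
    const double* yc = yp + M * c;
    const double* gc = gp + M * c;
    double* gxc = gxp + M * c;
    double s1 = 0, s2 = 0;
    bn_bwd_sums_d(xc, yc, gc, gxc, M, mu[c], invstd[c], relu, s1, s2);
    gbeta[c] = s1;
    ggamma[c] = s2;
    const double a = gamma[c] * invstd[c];
    if (use_batch) {
      bn_bwd_gx_d(xc, gxc, M, mu[c], invstd[c], a, s1 / M, s2 / M);
    } else {
      axpb_d(gxc, gxc, M, a, 0.0, false);
    }
  }
  gx.attr("dim") = xd;
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// ---- elementwise / pooling / resize helpers (double precision) --------------
// These replace memory-heavy R formulations with single-pass loops; they are
// bandwidth-bound, so they stay in doubles and skip the float round-trip.

// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector y(x.size());
  relu_d(x.begin(), y.begin(), x.size());
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector y, NumericVector g) {
  NumericVector gx(g.size());
  relu_mask_d(y.begin(), g.begin(), gx.begin(), g.size());
  gx.attr("dim") = g.attr("dim");
  return gx;
}

// y = relu(a + b)
// [[Rcpp::export]]
NumericVector cpp_add_relu_forward(NumericVector a, NumericVector b) {
  NumericVector y(a.size());
  add_relu_d(a.begin(), b.begin(), y.begin(), a.size());
  y.attr("dim") = a.attr("dim");
  return y;
}

// per-pixel mean and channel argmax over (H, W, N, C) -> (H, W, N, 2) + idx
// [[Rcpp::export]]
List cpp_channel_pool_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t M = (size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector y(2 * M);
  IntegerVector wm(M);
  const double* xp = x.begin();
  double* mean_p = y.begin();
  double* max_p = y.begin() + M;
  for (size_t i = 0; i < M; ++i) { mean_p[i] = 0.0; max_p[i] = -INFINITY; }
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + M * c;
    for (size_t i = 0; i < M; ++i) {
      mean_p[i] += xc[i];
      if (xc[i] > max_p[i]) { max_p[i] = xc[i]; wm[i] = c; }
    }
  }
  const double inv = 1.0 / C;
  for (size_t i = 0; i < M; ++i) mean_p[i] *= inv;
  y.attr("dim") = IntegerVector::create(xd[0], xd[1], xd[2], 2);
  return List::create(_["y"] = y, _["wm"] = wm);
}

// [[Rcpp::export]]
NumericVector cpp_channel_pool_backward(NumericVector g, IntegerVector wm,
                                        IntegerVector xdim) {
  const size_t M = (size_t)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector gx((R_xlen_t)M * C);
  const double* g1 = g.begin();       // mean map gradient
  const double* g2 = g.begin() + M;   // max map gradient
  double* gp = gx.begin();
  const double inv = 1.0 / C;
  for (int c = 0; c < C; ++c) {
    double* gc = gp + M * c;
    for (size_t i = 0; i < M; ++i) gc[i] = g1[i] * inv;
  }
  for (size_t i = 0; i < M; ++i) gp[M * (size_t)wm[i] + i] += g2[i];
  gx.attr("dim") = xdim;
  return gx;
}

// global average + max pool over H, W: (H, W, N, C) -> two (N, C) matrices
// [[Rcpp::export]]
List cpp_gap_gmp_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int NC = xd[2] * xd[3];
  NumericVector avg(NC), mx(NC);
  IntegerVector wm(NC);
  const double* xp = x.begin();
  for (int j = 0; j < NC; ++j) {
    const double* col = xp + HW * j;
    double s = 0, best = col[0]; int bi = 0;
    for (size_t i = 0; i < HW; ++i) {
      s += col[i];
      if (col[i] > best) { best = col[i]; bi = (int)i; }
    }
    avg[j] = s / HW; mx[j] = best; wm[j] = bi;
  }
  avg.attr("dim") = IntegerVector::create(xd[2], xd[3]);
  mx.attr("dim") = IntegerVector::create(xd[2], xd[3]);
  return List::create(_["avg"] = avg, _["max"] = mx, _["wm"] = wm);
}

// [[Rcpp::export]]
NumericVector cpp_gap_gmp_backward(NumericVector gavg, NumericVector gmax,
                                   IntegerVector wm, IntegerVector xdim) {
  const size_t HW = (size_t)xdim[0] * xdim[1];
  const int NC = xdim[2] * xdim[3];
  NumericVector gx((R_xlen_t)HW * NC);
  double* gp = gx.begin();
  const bool has_avg = gavg.size() > 0, has_max = gmax.size() > 0;
  for (int j = 0; j < NC; ++j) {
    double* col = gp + HW * j;
    if (has_avg) {
      const double v = gavg[j] / HW;
      for (size_t i = 0; i < HW; ++i) col[i] = v;
    }
    if (has_max) col[wm[j]] += gmax[j];
  }
  gx.attr("dim") = xdim;
  return gx;
}

// x (H, W, N, C) scaled by per-sample per-channel gates a (N, C)
// [[Rcpp::export]]
NumericVector cpp_scale_channels_forward(NumericVector x, NumericVector a) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int NC = xd[2] * xd[3];
  NumericVector y(x.size());
  const double* xp = x.begin(); double* yp = y.begin();
  for (int j = 0; j < NC; ++j) {
    axpb_d(xp + HW * j, yp + HW * j, HW, a[j], 0.0, false);
  }
  y.attr("dim") = xd;
  return y;
}

// [[Rcpp::export]]
List cpp_scale_channels_backward(NumericVector x, NumericVector a,
                                 NumericVector g) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int NC = xd[2] * xd[3];
  NumericVector gx(x.size()), ga(NC);
  const double* xp = x.begin(); const double* gp = g.begin();
  double* gxp = gx.begin();
  for (int j = 0; j < NC; ++j) {
    ga[j] = scale_dot_d(xp + HW * j, gp + HW * j, gxp + HW * j, HW, a[j]);
  }
  gx.attr("dim") = xd;
  ga.attr("dim") = IntegerVector::create(xd[2], xd[3]);
  return List::create(_["gx"] = gx, _["ga"] = ga);
}

// x (H, W, N, C) scaled by spatial map a (H, W, N, 1), broadcast over C
// [[Rcpp::export]]
NumericVector cpp_scale_spatial_forward(NumericVector x, NumericVector a) {
  IntegerVector xd = x.attr("dim");
  const size_t M = (size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector y(x.size());
  const double* xp = x.begin(); const double* ap = a.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) mul_d(xp + M * c, ap, yp + M * c, M);
  y.attr("dim") = xd;
  return y;
}

// [[Rcpp::export]]
List cpp_scale_spatial_backward(NumericVector x, NumericVector a,
                                NumericVector g) {
  IntegerVector xd = x.attr("dim");
  const size_t M = (size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector gx(x.size()), ga(M);
  const double* xp = x.begin(); const double* ap = a.begin();
  const double* gp = g.begin();
  double* gxp = gx.begin(); double* gap_ = ga.begin();
  for (size_t i = 0; i < M; ++i) gap_[i] = 0.0;
  for (int c = 0; c < C; ++c) {
    mul_acc_d(xp + M * c, gp + M * c, ap, gxp + M * c, gap_, M);
  }
  gx.attr("dim") = xd;
  ga.attr("dim") = IntegerVector::create(xd[0], xd[1], xd[2], 1);
  return List::create(_["gx"] = gx, _["ga"] = ga);
}

// separable bilinear resize of (H, W, N, C) to (oh, ow) with half-pixel
// centres; lo/hi/frac are passed from R's cached interpolation grids as
// 1-based index vectors and weights: out = (1-f)*in[lo] + f*in[hi].
static void resize_pass_h(const double* x, int H, int W, size_t NC,
                          const int* lo, const int* hi, const double* fr,
                          int oh, double* y) {
  // resample dim 1: x (H, W*NC) -> y (oh, W*NC)
  const size_t cols = (size_t)W * NC;
  for (size_t j = 0; j < cols; ++j) {
    const double* xc = x + (size_t)H * j;
    double* yc = y + (size_t)oh * j;
    for (int i = 0; i < oh; ++i)
      yc[i] = (1.0 - fr[i]) * xc[lo[i] - 1] + fr[i] * xc[hi[i] - 1];
  }
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_forward(NumericVector x,
                                          IntegerVector hlo, IntegerVector hhi,
                                          NumericVector hfr,
                                          IntegerVector wlo, IntegerVector whi,
                                          NumericVector wfr) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1];
  const size_t NC = (size_t)xd[2] * xd[3];
  const int oh = hlo.size(), ow = wlo.size();
  // pass 1: height
  std::vector<double> tmp((size_t)oh * W * NC);
  resize_pass_h(x.begin(), H, W, NC, hlo.begin(), hhi.begin(), hfr.begin(),
                oh, tmp.data());
  // pass 2: width — for each (n, c) plane, resample columns
  NumericVector y((R_xlen_t)oh * ow * NC);
  double* yp = y.begin();
  for (size_t p = 0; p < NC; ++p) {
    const double* tp = tmp.data() + (size_t)oh * W * p;
    double* yq = yp + (size_t)oh * ow * p;
    for (int j = 0; j < ow; ++j) {
      const double* c0 = tp + (size_t)oh * (wlo[j] - 1);
      const double* c1 = tp + (size_t)oh * (whi[j] - 1);
      const double f = wfr[j];
      double* yc = yq + (size_t)oh * j;
      for (int i = 0; i < oh; ++i) yc[i] = (1.0 - f) * c0[i] + f * c1[i];
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, xd[2], xd[3]);
  return y;
}

// adjoint of the bilinear resize: scatter-add with the same grids
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_backward(NumericVector g, int H, int W,
                                           IntegerVector hlo, IntegerVector hhi,
                                           NumericVector hfr,
                                           IntegerVector wlo, IntegerVector whi,
                                           NumericVector wfr) {
  IntegerVector gd = g.attr("dim");
  const int oh = gd[0], ow = gd[1];
  const size_t NC = (size_t)gd[2] * gd[3];
  // pass 1 (adjoint of width pass): g (oh, ow, NC) -> tmp (oh, W, NC)
  std::vector<double> tmp((size_t)oh * W * NC, 0.0);
  const double* gp = g.begin();
  for (size_t p = 0; p < NC; ++p) {
    const double* gq = gp + (size_t)oh * ow * p;
    double* tp = tmp.data() + (size_t)oh * W * p;
    for (int j = 0; j < ow; ++j) {
      const double* gc = gq + (size_t)oh * j;
      double* c0 = tp + (size_t)oh * (wlo[j] - 1);
      double* c1 = tp + (size_t)oh * (whi[j] - 1);
      const double f = wfr[j];
      for (int i = 0; i < oh; ++i) {
        c0[i] += (1.0 - f) * gc[i];
        c1[i] += f * gc[i];
      }
    }
  }
  // pass 2 (adjoint of height pass): tmp (oh, W*NC) -> gx (H, W*NC)
  NumericVector gx((R_xlen_t)H * W * NC);
  double* xp = gx.begin();
  const size_t cols = (size_t)W * NC;
  for (size_t j = 0; j < cols; ++j) {
    const double* tc = tmp.data() + (size_t)oh * j;
    double* xc = xp + (size_t)H * j;
    for (int i = 0; i < oh; ++i) {
      xc[hlo[i] - 1] += (1.0 - hfr[i]) * tc[i];
      xc[hhi[i] - 1] += hfr[i] * tc[i];
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, gd[2], gd[3]);
  return gx;
}

// channel concatenation (H, W, N, Cx) ++ (H, W, N, Cy) and its split adjoint
// [[Rcpp::export]]
NumericVector cpp_concat_c(NumericVector x, NumericVector y) {
  IntegerVector xd = x.attr("dim"), yd = y.attr("dim");
  NumericVector out(x.size() + y.size());
  std::memcpy(out.begin(), x.begin(), x.size() * sizeof(double));
  std::memcpy(out.begin() + x.size(), y.begin(), y.size() * sizeof(double));
  out.attr("dim") = IntegerVector::create(xd[0], xd[1], xd[2], xd[3] + yd[3]);
  return out;
}

// keep batch samples idx (1-based) of an (H, W, N, C) array
// [[Rcpp::export]]
NumericVector cpp_slice_n_forward(NumericVector x, IntegerVector idx) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int N = xd[2], C = xd[3], M = idx.size();
  NumericVector y((R_xlen_t)HW * M * C);
  const double* xp = x.begin(); double* yp = y.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < M; ++j)
      std::memcpy(yp + HW * ((size_t)j + (size_t)M * c),
                  xp + HW * ((size_t)(idx[j] - 1) + (size_t)N * c),
                  HW * sizeof(double));
  y.attr("dim") = IntegerVector::create(xd[0], xd[1], M, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_slice_n_backward(NumericVector g, IntegerVector idx, int N) {
  IntegerVector gd = g.attr("dim");
  const size_t HW = (size_t)gd[0] * gd[1];
  const int M = gd[2], C = gd[3];
  NumericVector gx((R_xlen_t)HW * N * C);   // zero-initialised
  const double* gp = g.begin(); double* xp = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < M; ++j) {
      double* dst = xp + HW * ((size_t)(idx[j] - 1) + (size_t)N * c);
      const double* src = gp + HW * ((size_t)j + (size_t)M * c);
      for (size_t i = 0; i < HW; ++i) dst[i] += src[i];
    }
  gx.attr("dim") = IntegerVector::create(gd[0], gd[1], N, C);
  return gx;
}

// a += b without allocating; callers must guarantee exclusive ownership of
// `a` (see accum_grad / accum_pgrad in R/autodiff.R for the ownership rule)
// [[Rcpp::export]]
void cpp_add_inplace(NumericVector a, NumericVector b) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("add_inplace: length mismatch");
  add_d(a.begin(), b.begin(), n);
}

// fused in-place Adam step over a list of parameter environments; each env
// holds $value, $grad, $m, $v (exclusively owned by the training loop).
// [[Rcpp::export]]
void cpp_adam_step(List params, double lr, int t, double beta1, double beta2,
                   double eps) {
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (int k = 0; k < params.size(); ++k) {
    Environment p = params[k];
    NumericVector value = p["value"], grad = p["grad"], m = p["m"], v = p["v"];
    adam_d(value.begin(), grad.begin(), m.begin(), v.begin(), value.size(),
           beta1, beta2, lr, c1, c2, eps);
  }
}
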