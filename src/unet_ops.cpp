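// Minimal 2D conv-net primitives used by the residual U-Net.
// Layout convention throughout: arrays are column-major R arrays with
// dim (H, W, C, N); convolutions are 'same'-padded with square kernels.
// im2col patch matrices are (H*W) x (C*k*k) so that GEMM output columns are
// contiguous per output channel.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void get_dim4(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4D array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// P: (H*W) x (C*k*k), column index r = (c*k + di)*k + dj
static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::mat& P) {
  P.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        int r = (c * k + di) * k + dj;
        double* Pr = P.colptr(r);
        for (int j = 0; j < W; ++j) {
          int j2 = j + dj - pad;
          if (j2 < 0 || j2 >= W) continue;
          int i0 = std::max(0, pad - di);
          int i1 = std::min(H, H + pad - di);
          const double* src = xc + (size_t)H * j2;
          double* dst = Pr + (size_t)H * j;
          for (int i = i0; i < i1; ++i) dst[i] = src[i + di - pad];
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& Gp, int H, int W, int C, int k,
                       int pad, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * H * W;
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        int r = (c * k + di) * k + dj;
        const double* Gr = Gp.colptr(r);
        for (int j = 0; j < W; ++j) {
          int j2 = j + dj - pad;
          if (j2 < 0 || j2 >= W) continue;
          int i0 = std::max(0, pad - di);
          int i1 = std::min(H, H + pad - di);
          const double* src = Gr + (size_t)H * j;
          double* dst = gc + (size_t)H * j2;
          for (int i = i0; i < i1; ++i) dst[i + di - pad] += src[i];
        }
      }
    }
  }
}

// weight matrix (C*k*k) x Cout from w dim (k, k, Cin, Cout)
static arma::mat weight_mat(const NumericVector& w, int k, int Cin, int Cout) {
  arma::mat Wm(Cin * k * k, Cout);
  const double* wp = REAL(w);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int di = 0; di < k; ++di)
        for (int dj = 0; dj < k; ++dj)
          Wm((c * k + di) * k + dj, co) =
            wp[di + k * (dj + k * (c + Cin * co))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector cppConvFwd(NumericVector x, NumericVector w, NumericVector b) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != wd[1] || wd[2] != C)
    stop("kernel must be (k, k, Cin, Cout) with Cin matching input");
  int k = wd[0], Cout = wd[3], pad = (k - 1) / 2;
  arma::mat Wm = weight_mat(w, k, C, Cout);
  NumericVector y(R_xlen_t(H) * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat P(H * W, C * k * k);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n) {
    im2col(xp + (size_t)n * H * W * C, H, W, C, k, pad, P);
    arma::mat Y = P * Wm;  // (H*W) x Cout
    for (int co = 0; co < Cout; ++co) {
      double* dst = yp + (size_t)n * H * W * Cout + (size_t)co * H * W;
      const double* src = Y.colptr(co);
      double bc = b[co];
      for (int p = 0; p < H * W; ++p) dst[p] = src[p] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cppConvBwd(NumericVector x, NumericVector w, NumericVector gy) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Cout = wd[3], pad = (k - 1) / 2;
  arma::mat Wm = weight_mat(w, k, C, Cout);
  NumericVector gx(R_xlen_t(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat gW(C * k * k, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat P(H * W, C * k * k);
  const double* xp = REAL(x);
  const double* gyp = REAL(gy);
  double* gxp = REAL(gx);
  for (int n = 0; n < N; ++n) {
    im2col(xp + (size_t)n * H * W * C, H, W, C, k, pad, P);
    arma::mat Gy(H * W, Cout);
    for (int co = 0; co < Cout; ++co)
      std::copy(gyp + (size_t)n * H * W * Cout + (size_t)co * H * W,
                gyp + (size_t)n * H * W * Cout + (size_t)(co + 1) * H * W,
                Gy.colptr(co));
    gW += P.t() * Gy;
    gb += arma::sum(Gy, 0).t();
    arma::mat Gp = Gy * Wm.t();  // (H*W) x (C*k*k)
    col2im_add(Gp, H, W, C, k, pad, gxp + (size_t)n * H * W * C);
  }
  NumericVector gwv(R_xlen_t(k) * k * C * Cout);
  gwv.attr("dim") = IntegerVector::create(k, k, C, Cout);
  double* gwp = REAL(gwv);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < C; ++c)
      for (int di = 0; di < k; ++di)
        for (int dj = 0; dj < k; ++dj)
          gwp[di + k * (dj + k * (c + C * co))] =
            gW((c * k + di) * k + dj, co);
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
List cppMaxPool2(NumericVector x) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  int h = H / 2, w2 = W / 2;
  NumericVector y(R_xlen_t(h) * w2 * C * N);
  IntegerVector idx(R_xlen_t(h) * w2 * C * N);
  y.attr("dim") = IntegerVector::create(h, w2, C, N);
  idx.attr("dim") = IntegerVector::create(h, w2, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* base = xp + (size_t)(n * C + c) * H * W;
      R_xlen_t off = (R_xlen_t)(n * C + c) * H * W;
      for (int j = 0; j < w2; ++j)
        for (int i = 0; i < h; ++i) {
          int i0 = 2 * i, j0 = 2 * j;
          int best = i0 + H * j0;
          double bv = base[best];
          int cand[3] = { i0 + 1 + H * j0, i0 + H * (j0 + 1),
                          i0 + 1 + H * (j0 + 1) };
          for (int t = 0; t < 3; ++t)
            if (base[cand[t]] > bv) { bv = base[cand[t]]; best = cand[t]; }
          yp[q] = bv;
          ip[q] = (int)(off + best);
          ++q;
        }
    }
  // note: column order of (i,j) loop above is j-major to keep y contiguous
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cppMaxUnpool2(NumericVector gy, IntegerVector idx,
                            IntegerVector xdim) {
  NumericVector gx(R_xlen_t(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  double* gxp = REAL(gx);
  const double* gyp = REAL(gy);
  const int* ip = INTEGER(idx);
  for (R_xlen_t q = 0; q < gy.size(); ++q) gxp[ip[q]] += gyp[q];
  return gx;
}

// [[Rcpp::export]]
NumericVector cppUpsample2(NumericVector x) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y(R_xlen_t(2 * H) * 2 * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (R_xlen_t s = 0; s < (R_xlen_t)C * N; ++s) {
    const double* xs = xp + s * H * W;
    double* ys = yp + s * 4 * H * W;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = xs[i + H * j];
        int i0 = 2 * i, j0 = 2 * j, HH = 2 * H;
        ys[i0 + HH * j0] = v;
        ys[i0 + 1 + HH * j0] = v;
        ys[i0 + HH * (j0 + 1)] = v;
        ys[i0 + 1 + HH * (j0 + 1)] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cppUpsample2Bwd(NumericVector gy) {
  int d[4]; get_dim4(gy, d);
  int HH = d[0], WW = d[1], C = d[2], N = d[3];
  int H = HH / 2, W = WW / 2;
  NumericVector gx(R_xlen_t(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = REAL(gy);
  double* xp = REAL(gx);
  for (R_xlen_t s = 0; s < (R_xlen_t)C * N; ++s) {
    const double* gs = gp + s * HH * WW;
    double* xs = xp + s * H * W;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        int i0 = 2 * i, j0 = 2 * j;
        xs[i + H * j] = gs[i0 + HH * j0] + gs[i0 + 1 + HH * j0] +
                        gs[i0 + HH * (j0 + 1)] + gs[i0 + 1 + HH * (j0 + 1)];
      }
  }
  return gx;
}

// ---- fused channel-wise ops (batch-norm / activation hot path) ----------

// per-channel mean and biased variance over (H, W, N)
// [[Rcpp::export]]
List cppChanStats(NumericVector x) {
  int d[4]; get_dim4(x, d);
  int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector mu(C), var(C);
  const double* xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + (size_t)(n * C + c) * HW;
      for (int i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double M = (double)HW * N;
    mu[c] = s / M;
    var[c] = s2 / M - mu[c] * mu[c];
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// y = x * a[channel] + b[channel]
// [[Rcpp::export]]
NumericVector cppChanScale(NumericVector x, NumericVector a,
                           NumericVector b) {
  int d[4]; get_dim4(x, d);
  int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = xp + (size_t)(n * C + c) * HW;
      double* q = yp + (size_t)(n * C + c) * HW;
      double ac = a[c], bc = b[c];
      for (int i = 0; i < HW; ++i) q[i] = p[i] * ac + bc;
    }
  return y;
}

// per-channel sums of dy and of dy * xhat (batch-norm gradient reductions)
// [[Rcpp::export]]
List cppChanSums(NumericVector dy, NumericVector xhat) {
  int d[4]; get_dim4(dy, d);
  int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector sdy(C), sdyx(C);
  const double* ap = REAL(dy);
  const double* bp = REAL(xhat);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = ap + (size_t)(n * C + c) * HW;
      const double* q = bp + (size_t)(n * C + c) * HW;
      double s = 0, sx = 0;
      for (int i = 0; i < HW; ++i) { s += p[i]; sx += p[i] * q[i]; }
      sdy[c] += s; sdyx[c] += sx;
    }
  return List::create(_["sdy"] = sdy, _["sdyx"] = sdyx);
}

// dx = coef[ch] * (M * dy - sdy[ch] - xhat * sdyx[ch])
// [[Rcpp::export]]
NumericVector cppBnBwdCore(NumericVector dy, NumericVector xhat,
                           NumericVector sdy, NumericVector sdyx,
                           NumericVector coef) {
  int d[4]; get_dim4(dy, d);
  int HW = d[0] * d[1], C = d[2], N = d[3];
  double M = (double)HW * N;
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* ap = REAL(dy);
  const double* bp = REAL(xhat);
  double* rp = REAL(dx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = ap + (size_t)(n * C + c) * HW;
      const double* q = bp + (size_t)(n * C + c) * HW;
      double* r = rp + (size_t)(n * C + c) * HW;
      double s = sdy[c], sx = sdyx[c], k = coef[c];
      for (int i = 0; i < HW; ++i) r[i] = k * (M * p[i] - s - q[i] * sx);
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector cppLrelu(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = REAL(x);
  double* q = REAL(y);
  for (R_xlen_t i = 0; i < x.size(); ++i)
    q[i] = p[i] > 0 ? p[i] : slope * p[i];
  return y;
}

// gradient through leaky ReLU given the pre-activation
// [[Rcpp::export]]
NumericVector cppLreluBwd(NumericVector dy, NumericVector xpre,
                          double slope) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* p = REAL(dy);
  const double* z = REAL(xpre);
  double* q = REAL(dx);
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    q[i] = z[i] > 0 ? p[i] : slope * p[i];
  return dx;
}
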