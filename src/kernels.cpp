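// Compiled numeric kernels: 3x3x3 (dilated) convolution via im2col + GEMM,
// and an exact anisotropic squared Euclidean distance transform.
//
// Tensor layout convention (column-major, matching R arrays):
//   feature tensors are (C, Z, Y, X, B); weights are (Cout, Cin*27) matrices
//   with column index c + Cin*j, where j = (dz+1) + 3*(dy+1) + 9*(dx+1)
//   enumerates kernel offsets. Convolutions are stride 1, zero-padded
//   ("same"), with a shared integer dilation on all axes.
//
// Two exactness-preserving optimizations matter at desk scale:
//   - taps whose dilated offset exceeds the volume extent on some axis are
//     dropped from the GEMM entirely (they contribute zero to every output
//     voxel, and their weight gradient is identically zero);
//   - all batch elements share one im2col buffer and one GEMM.
// GEMM runs in single precision by default (double the throughput of dgemm
// on one core); a double-precision path is kept for numerical checks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct TapBox {
  int j;                  // tap index
  int z0, z1, y0, y1, x0, x1;  // valid output box (half-open)
};

// For each kernel tap, the output box whose dilated source voxel lies
// inside the volume. Taps with an empty box contribute nothing to the
// output and have identically zero weight gradient.
std::vector<TapBox> tap_boxes(int Z, int Y, int X, int d) {
  std::vector<TapBox> boxes;
  for (int j = 0; j < 27; ++j) {
    const int dz = j % 3 - 1, dy = (j / 3) % 3 - 1, dx = j / 9 - 1;
    TapBox tb;
    tb.j = j;
    tb.z0 = std::max(0, -d * dz); tb.z1 = std::min(Z, Z - d * dz);
    tb.y0 = std::max(0, -d * dy); tb.y1 = std::min(Y, Y - d * dy);
    tb.x0 = std::max(0, -d * dx); tb.x1 = std::min(X, X - d * dx);
    if (tb.z0 < tb.z1 && tb.y0 < tb.y1 && tb.x0 < tb.x1) boxes.push_back(tb);
  }
  return boxes;
}

// Gather the source columns of a tap box into G (C x nj), z-runs contiguous.
template <typename T>
void gather_box(const T* xb, int C, int Z, int Y, const TapBox& tb,
                int d, arma::Mat<T>& G) {
  const int dz = tb.j % 3 - 1, dy = (tb.j / 3) % 3 - 1, dx = tb.j / 9 - 1;
  const int zrun = tb.z1 - tb.z0;
  T* g = G.memptr();
  for (int xo = tb.x0; xo < tb.x1; ++xo) {
    const int xs = xo + d * dx;
    for (int yo = tb.y0; yo < tb.y1; ++yo) {
      const int ys = yo + d * dy;
      const T* src = xb + (size_t)C *
        ((tb.z0 + d * dz) + (size_t)Z * (ys + (size_t)Y * xs));
      memcpy(g, src, sizeof(T) * C * zrun);
      g += (size_t)C * zrun;
    }
  }
}

template <typename T>
NumericVector conv3_fwd_impl(const NumericVector& x, const NumericMatrix& w,
                             const NumericVector& bias, int dilation, int C,
                             int Z, int Y, int X, int B, bool relu_out) {
  const int Cout = w.nrow();
  const size_t N = (size_t)Z * Y * X;
  const std::vector<TapBox> boxes = tap_boxes(Z, Y, X, dilation);
  arma::Mat<T> Wm(Cout, 27 * C);
  for (int jj = 0; jj < 27 * C; ++jj)
    for (int i = 0; i < Cout; ++i) Wm(i, jj) = (T)w(i, jj);
  arma::Col<T> bm(Cout);
  for (int i = 0; i < Cout; ++i) bm[i] = (T)bias[i];

  NumericVector out((size_t)Cout * N * B);
  out.attr("dim") = IntegerVector::create(Cout, Z, Y, X, B);
  arma::Mat<T> Of(Cout, N), xf(C, N);
  arma::Mat<T> G, Oj;
  for (int b = 0; b < B; ++b) {
    const double* xb = &x[(size_t)C * N * b];
    T* xp = xf.memptr();
    for (size_t i = 0; i < (size_t)C * N; ++i) xp[i] = (T)xb[i];
    Of.each_col() = bm;
    for (const TapBox& tb : boxes) {
      if (tb.j == 13) {  // centre tap: plain channel mixing, no gather
        Of += Wm.cols((size_t)C * 13, (size_t)C * 13 + C - 1) * xf;
        continue;
      }
      const size_t nj = (size_t)(tb.z1 - tb.z0) * (tb.y1 - tb.y0) *
                        (tb.x1 - tb.x0);
      G.set_size(C, nj);
      gather_box<T>(xf.memptr(), C, Z, Y, tb, dilation, G);
      Oj = Wm.cols((size_t)C * tb.j, (size_t)C * tb.j + C - 1) * G;
      // scatter-add back over the box, z-runs contiguous in both buffers
      const T* src = Oj.memptr();
      const int zrun = tb.z1 - tb.z0;
      for (int xo = tb.x0; xo < tb.x1; ++xo) {
        for (int yo = tb.y0; yo < tb.y1; ++yo) {
          T* dst = Of.memptr() + (size_t)Cout *
            (tb.z0 + (size_t)Z * (yo + (size_t)Y * xo));
          const int n = Cout * zrun;
          for (int i = 0; i < n; ++i) dst[i] += src[i];
          src += n;
        }
      }
    }
    double* op = &out[(size_t)Cout * N * b];
    const T* of = Of.memptr();
    if (relu_out) {
      for (size_t i = 0; i < (size_t)Cout * N; ++i)
        op[i] = of[i] > 0 ? (double)of[i] : 0.0;
    } else {
      for (size_t i = 0; i < (size_t)Cout * N; ++i) op[i] = (double)of[i];
    }
  }
  return out;
}

template <typename T>
List conv3_bwd_weight_impl(const NumericVector& x, const NumericVector& dy,
                           int Cout, int dilation, int C, int Z, int Y, int X,
                           int B) {
  const size_t N = (size_t)Z * Y * X;
  const std::vector<TapBox> boxes = tap_boxes(Z, Y, X, dilation);
  arma::Mat<T> dWv(Cout, 27 * C, arma::fill::zeros);
  arma::Col<T> db(Cout, arma::fill::zeros);
  arma::Mat<T> Df(Cout, N), xf(C, N);
  arma::Mat<T> G, D;
  for (int b = 0; b < B; ++b) {
    const double* xb = &x[(size_t)C * N * b];
    const double* dp = &dy[(size_t)Cout * N * b];
    T* q = Df.memptr();
    for (size_t i = 0; i < (size_t)Cout * N; ++i) q[i] = (T)dp[i];
    T* xp = xf.memptr();
    for (size_t i = 0; i < (size_t)C * N; ++i) xp[i] = (T)xb[i];
    db += arma::sum(Df, 1);
    for (const TapBox& tb : boxes) {
      if (tb.j == 13) {  // centre tap: no gathers needed
        dWv.cols((size_t)C * 13, (size_t)C * 13 + C - 1) += Df * xf.t();
        continue;
      }
      const size_t nj = (size_t)(tb.z1 - tb.z0) * (tb.y1 - tb.y0) *
                        (tb.x1 - tb.x0);
      G.set_size(C, nj);
      gather_box<T>(xf.memptr(), C, Z, Y, tb, dilation, G);
      // gather matching dY columns (float source, already cast)
      D.set_size(Cout, nj);
      T* g = D.memptr();
      const int zrun = tb.z1 - tb.z0;
      for (int xo = tb.x0; xo < tb.x1; ++xo) {
        for (int yo = tb.y0; yo < tb.y1; ++yo) {
          const T* src = Df.memptr() + (size_t)Cout *
            (tb.z0 + (size_t)Z * (yo + (size_t)Y * xo));
          memcpy(g, src, sizeof(T) * Cout * zrun);
          g += (size_t)Cout * zrun;
        }
      }
      dWv.cols((size_t)C * tb.j, (size_t)C * tb.j + C - 1) += D * G.t();
    }
  }
  NumericMatrix dWout(Cout, 27 * C);
  for (int jj = 0; jj < 27 * C; ++jj)
    for (int i = 0; i < Cout; ++i) dWout(i, jj) = (double)dWv(i, jj);
  NumericVector dbout(Cout);
  for (int i = 0; i < Cout; ++i) dbout[i] = (double)db[i];
  return List::create(_["dw"] = dWout, _["db"] = dbout);
}

}  // namespace

// [[Rcpp::export(name = ".conv3_fwd_cpp")]]
NumericVector conv3_fwd_cpp(NumericVector x, NumericMatrix w, NumericVector bias,
                            int dilation, bool use_double, bool relu_out) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 5) stop("input tensor must have dim (C, Z, Y, X, B)");
  const int C = dim[0], Z = dim[1], Y = dim[2], X = dim[3], B = dim[4];
  if (w.ncol() != 27 * C) stop("weight matrix has wrong number of columns");
  if (bias.size() != w.nrow()) stop("bias length must equal output channels");
  if (use_double)
    return conv3_fwd_impl<double>(x, w, bias, dilation, C, Z, Y, X, B, relu_out);
  return conv3_fwd_impl<float>(x, w, bias, dilation, C, Z, Y, X, B, relu_out);
}

// 2x2x2 max pooling with stride 2; returns pooled tensor and 1-based argmax
// linear indices into the input (first maximum wins on ties).
// [[Rcpp::export(name = ".maxpool_fwd_cpp")]]
List maxpool_fwd_cpp(NumericVector x) {
  IntegerVector dim = x.attr("dim");
  const int C = dim[0], Z = dim[1], Y = dim[2], X = dim[3], B = dim[4];
  const int Zo = Z / 2, Yo = Y / 2, Xo = X / 2;
  const size_t No = (size_t)Zo * Yo * Xo;
  NumericVector y(no_init((size_t)C * No * B));
  y.attr("dim") = IntegerVector::create(C, Zo, Yo, Xo, B);
  IntegerVector arg(no_init((size_t)C * No * B));
  double* yp = &y[0];
  int* ap = &arg[0];
  for (int b = 0; b < B; ++b) {
    const double* xb = &x[(size_t)C * Z * Y * X * b];
    const size_t boff = (size_t)C * Z * Y * X * b;
    for (int xo = 0; xo < Xo; ++xo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int zo = 0; zo < Zo; ++zo) {
          const size_t ocol = (size_t)C *
            (zo + (size_t)Zo * (yo + (size_t)Yo * xo)) + (size_t)C * No * b;
          for (int c = 0; c < C; ++c) {
            double best = -INFINITY;
            size_t besti = 0;
            for (int ox = 0; ox < 2; ++ox)
              for (int oy = 0; oy < 2; ++oy)
                for (int oz = 0; oz < 2; ++oz) {
                  const size_t ii = c + (size_t)C *
                    ((2 * zo + oz) + (size_t)Z *
                     ((2 * yo + oy) + (size_t)Y * (2 * xo + ox)));
                  if (xb[ii] > best) {
                    best = xb[ii];
                    besti = ii;
                  }
                }
            yp[ocol + c] = best;
            ap[ocol + c] = (int)(boff + besti) + 1;
          }
        }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// Weight/bias gradient: dW = dY K^T over the whole batch, db = rowsums.
// [[Rcpp::export(name = ".conv3_bwd_weight_cpp")]]
List conv3_bwd_weight_cpp(NumericVector x, NumericVector dy, int Cout,
                          int dilation, bool use_double) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 5) stop("input tensor must have dim (C, Z, Y, X, B)");
  const int C = dim[0], Z = dim[1], Y = dim[2], X = dim[3], B = dim[4];
  if (use_double)
    return conv3_bwd_weight_impl<double>(x, dy, Cout, dilation, C, Z, Y, X, B);
  return conv3_bwd_weight_impl<float>(x, dy, Cout, dilation, C, Z, Y, X, B);
}

// [[Rcpp::export(name = ".relu_fwd_cpp")]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector out(no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = x[i] > 0 ? x[i] : 0.0;
  return out;
}

// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericVector relu_bwd_cpp(NumericVector dy, NumericVector x) {
  NumericVector out(no_init(dy.size()));
  out.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i) out[i] = x[i] > 0 ? dy[i] : 0.0;
  return out;
}

// Group normalization forward: stats over (channels-in-group x space) per
// (group, batch element). Returns y plus what backward needs.
// [[Rcpp::export(name = ".gn_fwd_cpp")]]
List gn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                int G, double eps) {
  IntegerVector dim = x.attr("dim");
  const int C = dim[0];
  const size_t N = (size_t)dim[1] * dim[2] * dim[3];
  const int B = dim[4];
  const int Cg = C / G;
  NumericVector y(no_init(x.size())), xhat(no_init(x.size()));
  y.attr("dim") = dim;
  xhat.attr("dim") = dim;
  NumericMatrix sdv(G, B);
  std::vector<double> sum(G), sumsq(G), mu(G), isd(G);
  const double denom = (double)Cg * N;
  for (int b = 0; b < B; ++b) {
    std::fill(sum.begin(), sum.end(), 0.0);
    std::fill(sumsq.begin(), sumsq.end(), 0.0);
    const double* xb = &x[(size_t)C * N * b];
    for (size_t v = 0; v < N; ++v) {
      const double* col = xb + (size_t)C * v;
      for (int c = 0; c < C; ++c) {
        sum[c / Cg] += col[c];
        sumsq[c / Cg] += col[c] * col[c];
      }
    }
    for (int g = 0; g < G; ++g) {
      mu[g] = sum[g] / denom;
      const double var = sumsq[g] / denom - mu[g] * mu[g];
      sdv(g, b) = std::sqrt(var + eps);
      isd[g] = 1.0 / sdv(g, b);
    }
    double* yb = &y[(size_t)C * N * b];
    double* hb = &xhat[(size_t)C * N * b];
    for (size_t v = 0; v < N; ++v) {
      const size_t off = (size_t)C * v;
      for (int c = 0; c < C; ++c) {
        const double h = (xb[off + c] - mu[c / Cg]) * isd[c / Cg];
        hb[off + c] = h;
        yb[off + c] = gamma[c] * h + beta[c];
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["sdv"] = sdv);
}

// [[Rcpp::export(name = ".gn_bwd_cpp")]]
List gn_bwd_cpp(NumericVector dy, NumericVector xhat, NumericMatrix sdv,
                NumericVector gamma, int G) {
  IntegerVector dim = dy.attr("dim");
  const int C = dim[0];
  const size_t N = (size_t)dim[1] * dim[2] * dim[3];
  const int B = dim[4];
  const int Cg = C / G;
  NumericVector dx(no_init(dy.size()));
  dx.attr("dim") = dim;
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> m1(G), m2(G);
  const double denom = (double)Cg * N;
  for (int b = 0; b < B; ++b) {
    std::fill(m1.begin(), m1.end(), 0.0);
    std::fill(m2.begin(), m2.end(), 0.0);
    const double* db_ = &dy[(size_t)C * N * b];
    const double* hb = &xhat[(size_t)C * N * b];
    for (size_t v = 0; v < N; ++v) {
      const size_t off = (size_t)C * v;
      for (int c = 0; c < C; ++c) {
        const double d = db_[off + c], h = hb[off + c];
        dgamma[c] += d * h;
        dbeta[c] += d;
        const double dh = d * gamma[c];
        m1[c / Cg] += dh;
        m2[c / Cg] += dh * h;
      }
    }
    for (int g = 0; g < G; ++g) {
      m1[g] /= denom;
      m2[g] /= denom;
    }
    double* dxb = &dx[(size_t)C * N * b];
    for (size_t v = 0; v < N; ++v) {
      const size_t off = (size_t)C * v;
      for (int c = 0; c < C; ++c) {
        const int g = c / Cg;
        const double dh = db_[off + c] * gamma[c];
        dxb[off + c] = (dh - m1[g] - hb[off + c] * m2[g]) / sdv(g, b);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

namespace {

// Felzenszwalb & Huttenlocher 1D lower envelope of parabolas, with physical
// coordinate step s (mm). f holds squared distances; overwritten in place.
void dt1d(double* f, int n, int stride, double s, double* v_x, double* v_f,
          double* zb, double* out) {
  int k = 0;
  v_x[0] = 0.0;
  v_f[0] = f[0];
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    const double xq = q * s, fq = f[(size_t)q * stride];
    double sintr;
    for (;;) {
      const double xv = v_x[k], fv = v_f[k];
      sintr = ((fq + xq * xq) - (fv + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (sintr > zb[k]) break;
      --k;
    }
    ++k;
    v_x[k] = xq;
    v_f[k] = fq;
    zb[k] = sintr;
    zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (zb[k + 1] < xq) ++k;
    const double dx = xq - v_x[k];
    out[q] = dx * dx + v_f[k];
  }
  for (int q = 0; q < n; ++q) f[(size_t)q * stride] = out[q];
}

}  // namespace

// Squared Euclidean distance (mm^2) to the nearest true voxel; the caller
// guarantees the mask is non-empty. mask dims (Z, Y, X), spacing (sz, sy, sx).
// [[Rcpp::export(name = ".edt3_sq_cpp")]]
NumericVector edt3_sq_cpp(LogicalVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  const int Z = dim[0], Y = dim[1], X = dim[2];
  const double BIG = 1e30;
  NumericVector f((size_t)Z * Y * X);
  for (size_t i = 0; i < (size_t)Z * Y * X; ++i) f[i] = mask[i] ? 0.0 : BIG;
  f.attr("dim") = dim;

  const int nmax = std::max(Z, std::max(Y, X));
  std::vector<double> v_x(nmax), v_f(nmax), zb(nmax + 1), out(nmax);

  for (int x = 0; x < X; ++x)  // along z
    for (int y = 0; y < Y; ++y)
      dt1d(&f[(size_t)Z * (y + (size_t)Y * x)], Z, 1, spacing[0], v_x.data(),
           v_f.data(), zb.data(), out.data());
  for (int x = 0; x < X; ++x)  // along y
    for (int z = 0; z < Z; ++z)
      dt1d(&f[z + (size_t)Z * Y * x], Y, Z, spacing[1], v_x.data(), v_f.data(),
           zb.data(), out.data());
  for (int y = 0; y < Y; ++y)  // along x
    for (int z = 0; z < Z; ++z)
      dt1d(&f[z + (size_t)Z * y], X, Z * Y, spacing[2], v_x.data(), v_f.data(),
           zb.data(), out.data());
  return f;
}
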