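// Dense N-d convolution via im2col + BLAS matrix products.
//
// All convolutions in the package (1-D along the spectral axis, 3-D over
// rows x cols x bands) go through the same 3-D kernel: a 1-D convolution is
// a 3-D convolution with singleton spatial dimensions.  Input tensors are
// column-major R arrays of shape (d1, d2, d3, Cin, N); weights are a
// (k1*k2*k3*Cin) x Cout matrix whose row index is the column-major
// flattening of (i1, i2, i3, c).
//
// The optimizer path (use_float = true) runs the GEMMs in single
// precision, which halves the memory traffic of the dominant operation;
// evaluation and saliency passes use double precision throughout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int d, int k, int s, int p) {
  return (d + 2 * p - k) / s + 1;
}

struct ConvGeom {
  int d1, d2, d3, cin, n;
  int k1, k2, k3, s1, s2, s3, p1, p2, p3;
  int o1, o2, o3, K, P;
};

static ConvGeom geom(IntegerVector xdim, IntegerVector kern,
                     IntegerVector stride, IntegerVector pad) {
  ConvGeom g;
  g.d1 = xdim[0]; g.d2 = xdim[1]; g.d3 = xdim[2];
  g.cin = xdim[3]; g.n = xdim[4];
  g.k1 = kern[0]; g.k2 = kern[1]; g.k3 = kern[2];
  g.s1 = stride[0]; g.s2 = stride[1]; g.s3 = stride[2];
  g.p1 = pad[0]; g.p2 = pad[1]; g.p3 = pad[2];
  g.o1 = out_size(g.d1, g.k1, g.s1, g.p1);
  g.o2 = out_size(g.d2, g.k2, g.s2, g.p2);
  g.o3 = out_size(g.d3, g.k3, g.s3, g.p3);
  g.K = g.k1 * g.k2 * g.k3 * g.cin;
  g.P = g.o1 * g.o2 * g.o3;
  return g;
}

// Fill the im2col matrix (K x P) for one sample.  x points at that sample's
// (d1, d2, d3, Cin) block.  Out-of-range taps are zero (zero padding).
template <typename T>
static void im2col(const double* x, arma::Mat<T>& col, const ConvGeom& g) {
  col.zeros();
  for (int j3 = 0; j3 < g.o3; ++j3) {
    for (int j2 = 0; j2 < g.o2; ++j2) {
      for (int j1 = 0; j1 < g.o1; ++j1) {
        const int p = j1 + g.o1 * (j2 + g.o2 * j3);
        T* cp = col.colptr(p);
        for (int c = 0; c < g.cin; ++c) {
          for (int i3 = 0; i3 < g.k3; ++i3) {
            const int x3 = j3 * g.s3 - g.p3 + i3;
            if (x3 < 0 || x3 >= g.d3) continue;
            for (int i2 = 0; i2 < g.k2; ++i2) {
              const int x2 = j2 * g.s2 - g.p2 + i2;
              if (x2 < 0 || x2 >= g.d2) continue;
              const double* xb = x + g.d1 * (x2 + g.d2 * (x3 + g.d3 * c));
              T* cb = cp + g.k1 * (i2 + g.k2 * (i3 + g.k3 * c));
              const int lo = std::max(0, g.p1 - j1 * g.s1);
              const int hi = std::min(g.k1, g.d1 - j1 * g.s1 + g.p1);
              for (int i1 = lo; i1 < hi; ++i1) {
                cb[i1] = static_cast<T>(xb[j1 * g.s1 - g.p1 + i1]);
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add of a column gradient back onto the input gradient (col2im).
template <typename T>
static void col2im(const arma::Mat<T>& col, double* dx, const ConvGeom& g) {
  for (int j3 = 0; j3 < g.o3; ++j3) {
    for (int j2 = 0; j2 < g.o2; ++j2) {
      for (int j1 = 0; j1 < g.o1; ++j1) {
        const int p = j1 + g.o1 * (j2 + g.o2 * j3);
        const T* cp = col.colptr(p);
        for (int c = 0; c < g.cin; ++c) {
          for (int i3 = 0; i3 < g.k3; ++i3) {
            const int x3 = j3 * g.s3 - g.p3 + i3;
            if (x3 < 0 || x3 >= g.d3) continue;
            for (int i2 = 0; i2 < g.k2; ++i2) {
              const int x2 = j2 * g.s2 - g.p2 + i2;
              if (x2 < 0 || x2 >= g.d2) continue;
              double* xb = dx + g.d1 * (x2 + g.d2 * (x3 + g.d3 * c));
              const T* cb = cp + g.k1 * (i2 + g.k2 * (i3 + g.k3 * c));
              const int lo = std::max(0, g.p1 - j1 * g.s1);
              const int hi = std::min(g.k1, g.d1 - j1 * g.s1 + g.p1);
              for (int i1 = lo; i1 < hi; ++i1) {
                xb[j1 * g.s1 - g.p1 + i1] += static_cast<double>(cb[i1]);
              }
            }
          }
        }
      }
    }
  }
}

// Persistent scratch buffers (single-threaded use); avoids repeated large
// allocations in the training loop.
template <typename T>
static T* scratch(size_t need, int slot) {
  static std::vector<T> bufs[3];
  if (bufs[slot].size() < need) bufs[slot].resize(need);
  return bufs[slot].data();
}

template <typename T>
static void forward_impl(const double* x, const ConvGeom& g,
                         const NumericMatrix& W, const NumericVector& b,
                         double* y) {
  arma::Mat<T> Wm(g.K, W.ncol());
  for (int j = 0; j < W.ncol(); ++j) {
    for (int i = 0; i < g.K; ++i) Wm(i, j) = static_cast<T>(W(i, j));
  }
  arma::Row<T> bv(W.ncol());
  for (int j = 0; j < W.ncol(); ++j) bv[j] = static_cast<T>(b[j]);
  arma::Mat<T> col(scratch<T>(static_cast<size_t>(g.K) * g.P, 0),
                   g.K, g.P, false, true);
  arma::Mat<T> yt(scratch<T>(static_cast<size_t>(g.P) * W.ncol(), 1),
                  g.P, W.ncol(), false, true);
  const size_t xstep = static_cast<size_t>(g.d1) * g.d2 * g.d3 * g.cin;
  const size_t ystep = static_cast<size_t>(g.P) * W.ncol();
  for (int s = 0; s < g.n; ++s) {
    im2col<T>(x + s * xstep, col, g);
    yt = col.t() * Wm;
    yt.each_row() += bv;
    double* yp = y + s * ystep;
    const T* sp = yt.memptr();
    for (size_t i = 0; i < ystep; ++i) yp[i] = static_cast<double>(sp[i]);
  }
}

// [[Rcpp::export]]
NumericVector conv_nd_forward(NumericVector x, IntegerVector xdim,
                              NumericMatrix W, NumericVector b,
                              IntegerVector kern, IntegerVector stride,
                              IntegerVector pad, bool use_float = false) {
  const ConvGeom g = geom(xdim, kern, stride, pad);
  if (g.o1 < 1 || g.o2 < 1 || g.o3 < 1)
    stop("convolution output collapses to zero size");
  if (W.nrow() != g.K) stop("weight rows do not match kernel taps");
  NumericVector y(static_cast<R_xlen_t>(g.P) * W.ncol() * g.n);
  if (use_float) {
    forward_impl<float>(x.begin(), g, W, b, y.begin());
  } else {
    forward_impl<double>(x.begin(), g, W, b, y.begin());
  }
  y.attr("dim") = IntegerVector::create(g.o1, g.o2, g.o3, W.ncol(), g.n);
  return y;
}

template <typename T>
static void backward_impl(const double* x, const ConvGeom& g,
                          const NumericMatrix& W, const double* dy,
                          bool need_dx, double* dx, double* dWout,
                          double* dbout);

// In-place variant writing into a caller-owned buffer (the training hot
// path reuses output buffers across iterations to avoid allocation and
// page-fault overhead).
// [[Rcpp::export]]
void conv_fwd_ip(NumericVector x, IntegerVector xdim, NumericMatrix W,
                 NumericVector b, IntegerVector kern, IntegerVector stride,
                 IntegerVector pad, bool use_float, NumericVector y) {
  const ConvGeom g = geom(xdim, kern, stride, pad);
  if (g.o1 < 1 || g.o2 < 1 || g.o3 < 1)
    stop("convolution output collapses to zero size");
  if (W.nrow() != g.K) stop("weight rows do not match kernel taps");
  if (y.size() != static_cast<R_xlen_t>(g.P) * W.ncol() * g.n)
    stop("output buffer has the wrong size");
  if (use_float) {
    forward_impl<float>(x.begin(), g, W, b, y.begin());
  } else {
    forward_impl<double>(x.begin(), g, W, b, y.begin());
  }
}

// [[Rcpp::export]]
void conv_bwd_ip(NumericVector x, IntegerVector xdim, NumericMatrix W,
                 NumericVector dy, IntegerVector kern, IntegerVector stride,
                 IntegerVector pad, bool need_dx, bool use_float,
                 NumericVector dx, NumericMatrix dW, NumericVector db) {
  const ConvGeom g = geom(xdim, kern, stride, pad);
  if (need_dx) {
    if (dx.size() != x.size()) stop("dx buffer has the wrong size");
    std::fill(dx.begin(), dx.end(), 0.0);
  }
  if (use_float) {
    backward_impl<float>(x.begin(), g, W, dy.begin(), need_dx, dx.begin(),
                         dW.begin(), db.begin());
  } else {
    backward_impl<double>(x.begin(), g, W, dy.begin(), need_dx, dx.begin(),
                          dW.begin(), db.begin());
  }
}

// Gather samples (last axis) into a caller-owned batch buffer.
// [[Rcpp::export]]
void gather_samples(NumericVector x, IntegerVector xdim, IntegerVector idx,
                    NumericVector out) {
  R_xlen_t step = 1;
  for (int i = 0; i < xdim.size() - 1; ++i) step *= xdim[i];
  if (out.size() != step * idx.size()) stop("batch buffer size mismatch");
  for (int j = 0; j < idx.size(); ++j) {
    std::copy(x.begin() + (idx[j] - 1) * step,
              x.begin() + static_cast<R_xlen_t>(idx[j]) * step,
              out.begin() + j * step);
  }
}

template <typename T>
static void backward_impl(const double* x, const ConvGeom& g,
                          const NumericMatrix& W, const double* dy,
                          bool need_dx, double* dx, double* dWout,
                          double* dbout) {
  const int cout = W.ncol();
  arma::Mat<T> Wm(g.K, cout);
  for (int j = 0; j < cout; ++j) {
    for (int i = 0; i < g.K; ++i) Wm(i, j) = static_cast<T>(W(i, j));
  }
  arma::Mat<T> col(scratch<T>(static_cast<size_t>(g.K) * g.P, 0),
                   g.K, g.P, false, true);
  arma::Mat<T> dyt(scratch<T>(static_cast<size_t>(g.P) * cout, 1),
                   g.P, cout, false, true);
  arma::Mat<T> dW(g.K, cout, arma::fill::zeros);
  arma::Col<T> db(cout, arma::fill::zeros);
  const size_t xstep = static_cast<size_t>(g.d1) * g.d2 * g.d3 * g.cin;
  const size_t ystep = static_cast<size_t>(g.P) * cout;
  for (int s = 0; s < g.n; ++s) {
    const double* dp = dy + s * ystep;
    T* dytp = dyt.memptr();
    for (size_t i = 0; i < ystep; ++i) dytp[i] = static_cast<T>(dp[i]);
    im2col<T>(x + s * xstep, col, g);
    dW += col * dyt;
    db += arma::sum(dyt, 0).t();
    if (need_dx) {
      arma::Mat<T> dcol(scratch<T>(static_cast<size_t>(g.K) * g.P, 2),
                        g.K, g.P, false, true);
      dcol = Wm * dyt.t();
      col2im<T>(dcol, dx + s * xstep, g);
    }
  }
  const T* dwp = dW.memptr();
  for (int i = 0; i < g.K * cout; ++i) dWout[i] = static_cast<double>(dwp[i]);
  for (int j = 0; j < cout; ++j) dbout[j] = static_cast<double>(db[j]);
}

// [[Rcpp::export]]
List conv_nd_backward(NumericVector x, IntegerVector xdim,
                      NumericMatrix W, NumericVector dy,
                      IntegerVector kern, IntegerVector stride,
                      IntegerVector pad, bool need_dx,
                      bool use_float = false) {
  const ConvGeom g = geom(xdim, kern, stride, pad);
  const int cout = W.ncol();
  NumericVector dx(need_dx ? x.size() : R_xlen_t(0));
  NumericMatrix dW(g.K, cout);
  NumericVector db(cout);
  if (use_float) {
    backward_impl<float>(x.begin(), g, W, dy.begin(), need_dx, dx.begin(),
                         dW.begin(), db.begin());
  } else {
    backward_impl<double>(x.begin(), g, W, dy.begin(), need_dx, dx.begin(),
                          dW.begin(), db.begin());
  }
  if (need_dx) dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
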