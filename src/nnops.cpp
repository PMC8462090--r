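// One-pass elementwise kernels for the network hot path: batch
// normalization and ReLU.  These are memory-bound; doing them in compiled
// code avoids the temporary copies of the equivalent R expressions.

#include <Rcpp.h>
using namespace Rcpp;

// x flattened as (S, C, N).  Returns y and xhat; per-channel statistics are
// computed over S and N in training mode, taken from the running estimates
// otherwise.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, int S, int C, int N,
            NumericVector gamma, NumericVector beta,
            NumericVector running_mean, NumericVector running_var,
            double momentum, double eps, bool training) {
  const R_xlen_t len = x.size();
  NumericVector mu(C), v(C);
  if (training) {
    const double m = static_cast<double>(S) * N;
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c) {
        const double* xp = x.begin() + (static_cast<R_xlen_t>(n) * C + c) * S;
        double s = 0, sq = 0;
        for (int i = 0; i < S; ++i) {
          s += xp[i];
          sq += xp[i] * xp[i];
        }
        mu[c] += s;
        v[c] += sq;
      }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] /= m;
      v[c] = v[c] / m - mu[c] * mu[c];
      if (v[c] < 0) v[c] = 0;
    }
  } else {
    mu = clone(running_mean);
    v = clone(running_var);
  }
  NumericVector invstd(C), new_rm(C), new_rv(C);
  for (int c = 0; c < C; ++c) {
    invstd[c] = 1.0 / std::sqrt(v[c] + eps);
    new_rm[c] = training ?
      momentum * running_mean[c] + (1 - momentum) * mu[c] : running_mean[c];
    new_rv[c] = training ?
      momentum * running_var[c] + (1 - momentum) * v[c] : running_var[c];
  }
  NumericVector y(len), xhat(len);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (static_cast<R_xlen_t>(n) * C + c) * S;
      const double mc = mu[c], ic = invstd[c], gc = gamma[c], bc = beta[c];
      for (int i = 0; i < S; ++i) {
        const double xh = (x[off + i] - mc) * ic;
        xhat[off + i] = xh;
        y[off + i] = gc * xh + bc;
      }
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["xhat"] = xhat,
                      _["invstd"] = invstd,
                      _["running_mean"] = new_rm, _["running_var"] = new_rv);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector dy, NumericVector xhat, int S, int C, int N,
            NumericVector gamma, NumericVector invstd, bool training) {
  const double m = static_cast<double>(S) * N;
  NumericVector sum_dy(C), sum_dyx(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (static_cast<R_xlen_t>(n) * C + c) * S;
      double s = 0, sx = 0;
      for (int i = 0; i < S; ++i) {
        s += dy[off + i];
        sx += dy[off + i] * xhat[off + i];
      }
      sum_dy[c] += s;
      sum_dyx[c] += sx;
    }
  }
  NumericVector dx(dy.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (static_cast<R_xlen_t>(n) * C + c) * S;
      const double gi = gamma[c] * invstd[c];
      if (training) {
        const double t1 = gi * sum_dy[c] / m;
        const double t2 = gi * sum_dyx[c] / m;
        for (int i = 0; i < S; ++i) {
          dx[off + i] = gi * dy[off + i] - t1 - xhat[off + i] * t2;
        }
      } else {
        for (int i = 0; i < S; ++i) dx[off + i] = gi * dy[off + i];
      }
    }
  }
  dx.attr("dim") = dy.attr("dim");
  return List::create(_["dx"] = dx, _["g_gamma"] = sum_dyx,
                      _["g_beta"] = sum_dy);
}

// Fused batch-norm + ReLU, the pre-activation pattern used throughout the
// residual trunk.  One fewer full pass over the activations in each
// direction than separate layers.
// [[Rcpp::export]]
List bnrelu_fwd(NumericVector x, int S, int C, int N,
                NumericVector gamma, NumericVector beta,
                NumericVector running_mean, NumericVector running_var,
                double momentum, double eps, bool training) {
  NumericVector mu(C), v(C);
  if (training) {
    const double m = static_cast<double>(S) * N;
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c) {
        const double* xp = x.begin() + (static_cast<R_xlen_t>(n) * C + c) * S;
        double s = 0, sq = 0;
        for (int i = 0; i < S; ++i) {
          s += xp[i];
          sq += xp[i] * xp[i];
        }
        mu[c] += s;
        v[c] += sq;
      }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] /= m;
      v[c] = v[c] / m - mu[c] * mu[c];
      if (v[c] < 0) v[c] = 0;
    }
  } else {
    mu = clone(running_mean);
    v = clone(running_var);
  }
  NumericVector invstd(C), new_rm(C), new_rv(C);
  for (int c = 0; c < C; ++c) {
    invstd[c] = 1.0 / std::sqrt(v[c] + eps);
    new_rm[c] = training ?
      momentum * running_mean[c] + (1 - momentum) * mu[c] : running_mean[c];
    new_rv[c] = training ?
      momentum * running_var[c] + (1 - momentum) * v[c] : running_var[c];
  }
  NumericVector y(x.size()), xhat(x.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (static_cast<R_xlen_t>(n) * C + c) * S;
      const double mc = mu[c], ic = invstd[c], gc = gamma[c], bc = beta[c];
      for (int i = 0; i < S; ++i) {
        const double xh = (x[off + i] - mc) * ic;
        xhat[off + i] = xh;
        const double z = gc * xh + bc;
        y[off + i] = z > 0 ? z : 0;
      }
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["xhat"] = xhat,
                      _["invstd"] = invstd,
                      _["running_mean"] = new_rm, _["running_var"] = new_rv);
}

// [[Rcpp::export]]
List bnrelu_bwd(NumericVector dy, NumericVector xhat, NumericVector y,
                int S, int C, int N, NumericVector gamma,
                NumericVector invstd, bool training) {
  const double m = static_cast<double>(S) * N;
  NumericVector sum_dy(C), sum_dyx(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (static_cast<R_xlen_t>(n) * C + c) * S;
      double s = 0, sx = 0;
      for (int i = 0; i < S; ++i) {
        if (y[off + i] > 0) {
          s += dy[off + i];
          sx += dy[off + i] * xhat[off + i];
        }
      }
      sum_dy[c] += s;
      sum_dyx[c] += sx;
    }
  }
  NumericVector dx(dy.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (static_cast<R_xlen_t>(n) * C + c) * S;
      const double gi = gamma[c] * invstd[c];
      if (training) {
        const double t1 = gi * sum_dy[c] / m;
        const double t2 = gi * sum_dyx[c] / m;
        for (int i = 0; i < S; ++i) {
          const double d = y[off + i] > 0 ? dy[off + i] : 0;
          dx[off + i] = gi * d - t1 - xhat[off + i] * t2;
        }
      } else {
        for (int i = 0; i < S; ++i) {
          dx[off + i] = y[off + i] > 0 ? gi * dy[off + i] : 0;
        }
      }
    }
  }
  dx.attr("dim") = dy.attr("dim");
  return List::create(_["dx"] = dx, _["g_gamma"] = sum_dyx,
                      _["g_beta"] = sum_dy);
}

// In-place fused BN + ReLU writing into caller-owned y / xhat buffers.
// [[Rcpp::export]]
List bnrelu_fwd_ip(NumericVector x, int S, int C, int N,
                   NumericVector gamma, NumericVector beta,
                   NumericVector running_mean, NumericVector running_var,
                   double momentum, double eps, bool training,
                   NumericVector y, NumericVector xhat) {
  if (y.size() != x.size() || xhat.size() != x.size())
    stop("bnrelu buffers have the wrong size");
  NumericVector mu(C), v(C);
  if (training) {
    const double m = static_cast<double>(S) * N;
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c) {
        const double* xp = x.begin() + (static_cast<R_xlen_t>(n) * C + c) * S;
        double s = 0, sq = 0;
        for (int i = 0; i < S; ++i) {
          s += xp[i];
          sq += xp[i] * xp[i];
        }
        mu[c] += s;
        v[c] += sq;
      }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] /= m;
      v[c] = v[c] / m - mu[c] * mu[c];
      if (v[c] < 0) v[c] = 0;
    }
  } else {
    mu = clone(running_mean);
    v = clone(running_var);
  }
  NumericVector invstd(C), new_rm(C), new_rv(C);
  for (int c = 0; c < C; ++c) {
    invstd[c] = 1.0 / std::sqrt(v[c] + eps);
    new_rm[c] = training ?
      momentum * running_mean[c] + (1 - momentum) * mu[c] : running_mean[c];
    new_rv[c] = training ?
      momentum * running_var[c] + (1 - momentum) * v[c] : running_var[c];
  }
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (static_cast<R_xlen_t>(n) * C + c) * S;
      const double mc = mu[c], ic = invstd[c], gc = gamma[c], bc = beta[c];
      for (int i = 0; i < S; ++i) {
        const double xh = (x[off + i] - mc) * ic;
        xhat[off + i] = xh;
        const double z = gc * xh + bc;
        y[off + i] = z > 0 ? z : 0;
      }
    }
  }
  return List::create(_["invstd"] = invstd, _["running_mean"] = new_rm,
                      _["running_var"] = new_rv);
}

// [[Rcpp::export]]
List bnrelu_bwd_ip(NumericVector dy, NumericVector xhat, NumericVector y,
                   int S, int C, int N, NumericVector gamma,
                   NumericVector invstd, bool training, NumericVector dx) {
  if (dx.size() != dy.size()) stop("dx buffer has the wrong size");
  const double m = static_cast<double>(S) * N;
  NumericVector sum_dy(C), sum_dyx(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (static_cast<R_xlen_t>(n) * C + c) * S;
      double s = 0, sx = 0;
      for (int i = 0; i < S; ++i) {
        if (y[off + i] > 0) {
          s += dy[off + i];
          sx += dy[off + i] * xhat[off + i];
        }
      }
      sum_dy[c] += s;
      sum_dyx[c] += sx;
    }
  }
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (static_cast<R_xlen_t>(n) * C + c) * S;
      const double gi = gamma[c] * invstd[c];
      if (training) {
        const double t1 = gi * sum_dy[c] / m;
        const double t2 = gi * sum_dyx[c] / m;
        for (int i = 0; i < S; ++i) {
          const double d = y[off + i] > 0 ? dy[off + i] : 0;
          dx[off + i] = gi * d - t1 - xhat[off + i] * t2;
        }
      } else {
        for (int i = 0; i < S; ++i) {
          dx[off + i] = y[off + i] > 0 ? gi * dy[off + i] : 0;
        }
      }
    }
  }
  return List::create(_["g_gamma"] = sum_dyx, _["g_beta"] = sum_dy);
}

// In-place elementwise accumulate: a += b (residual additions).
// [[Rcpp::export]]
void add_ip(NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("size mismatch in add_ip");
  for (R_xlen_t i = 0; i < a.size(); ++i) a[i] += b[i];
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
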