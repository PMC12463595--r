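#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Marginal log-likelihood (and analytic gradient) of the adjacent-categories
// GPCM with uniform-DIF offsets, ability integrated out by Gauss-Hermite
// quadrature. Persons sharing a covariate pattern share category
// probabilities, so probabilities are computed once per
// (item, pattern, node) cell; with a 2x4x3 demographic design that is at
// most 24 patterns regardless of sample size.
//
// Model: log P(Y=r)/P(Y=r-1) = beta_i * (theta - delta_ir - x'gamma_i),
// so the cumulative logit of category h is
//   z_h = beta_i * (h*theta - sum_{r<=h} delta_ir - h * x'gamma_i).
//
// Y: n x I, codes 0..m_i, NA_INTEGER = missing
// pat: n, 0-based covariate-pattern index into rows of Xu (P x K)
// delta: I x maxm (only first m[i] entries of row i used)
// nodes/wts: standard-normal quadrature nodes and weights; theta = sigma*node
// [[Rcpp::export]]
List gpcm_loglik_cpp(IntegerMatrix Y, IntegerVector pat, NumericMatrix Xu,
                     NumericVector beta, NumericMatrix delta, IntegerVector m,
                     NumericMatrix gamma, double sigma, NumericVector nodes,
                     NumericVector wts, bool want_grad) {
  const int n = Y.nrow(), I = Y.ncol(), P = Xu.nrow(), K = Xu.ncol(),
            Q = nodes.size();
  int maxm = 0;
  for (int i = 0; i < I; ++i) if (m[i] > maxm) maxm = m[i];
  const int H = maxm + 1;

  // per-item per-pattern DIF offset o_ip = x_p' gamma_i
  std::vector<double> off((size_t)I * P);
  for (int i = 0; i < I; ++i)
    for (int p = 0; p < P; ++p) {
      double o = 0.0;
      for (int k = 0; k < K; ++k) o += Xu(p, k) * gamma(i, k);
      off[(size_t)i * P + p] = o;
    }

  // category probabilities per (i, p, q)
  std::vector<double> prob((size_t)I * P * Q * H, 0.0);
  std::vector<double> cumd(H, 0.0);
  for (int i = 0; i < I; ++i) {
    const int mi = m[i];
    cumd[0] = 0.0;
    for (int h = 1; h <= mi; ++h) cumd[h] = cumd[h - 1] + delta(i, h - 1);
    for (int p = 0; p < P; ++p) {
      const double o = off[(size_t)i * P + p];
      for (int q = 0; q < Q; ++q) {
        const double th = sigma * nodes[q];
        double zmax = 0.0;
        double z[64];
        for (int h = 0; h <= mi; ++h) {
          z[h] = beta[i] * (h * th - cumd[h] - h * o);
          if (z[h] > zmax) zmax = z[h];
        }
        double s = 0.0;
        for (int h = 0; h <= mi; ++h) { z[h] = std::exp(z[h] - zmax); s += z[h]; }
        double *pr = &prob[(((size_t)i * P + p) * Q + q) * H];
        for (int h = 0; h <= mi; ++h) pr[h] = z[h] / s;
      }
    }
  }

  // per-person per-node joint probability of the observed response vector
  std::vector<double> joint((size_t)n * Q);
  double loglik = 0.0;
  for (int v = 0; v < n; ++v) {
    const int p = pat[v];
    double L = 0.0;
    for (int q = 0; q < Q; ++q) {
      double f = wts[q];
      for (int i = 0; i < I; ++i) {
        const int y = Y(v, i);
        if (y == NA_INTEGER) continue;
        f *= prob[(((size_t)i * P + p) * Q + q) * H + y];
      }
      joint[(size_t)v * Q + q] = f;
      L += f;
    }
    if (L < 1e-300) L = 1e-300;
    loglik += std::log(L);
    // convert joint into posterior weights for the gradient pass
    if (want_grad)
      for (int q = 0; q < Q; ++q) joint[(size_t)v * Q + q] /= L;
  }

  if (!want_grad) return List::create(_["loglik"] = loglik);

  // posterior-weighted observed-category counts per (i, p, q, h)
  std::vector<double> A((size_t)I * P * Q * H, 0.0);
  for (int v = 0; v < n; ++v) {
    const int p = pat[v];
    for (int i = 0; i < I; ++i) {
      const int y = Y(v, i);
      if (y == NA_INTEGER) continue;
      double *a = &A[(((size_t)i * P + p) * Q) * H];
      const double *post = &joint[(size_t)v * Q];
      for (int q = 0; q < Q; ++q) a[q * H + y] += post[q];
    }
  }

  NumericVector gbeta(I), gsigma(1);
  NumericMatrix gdelta(I, maxm), ggamma(I, K);
  gsigma[0] = 0.0;
  for (int i = 0; i < I; ++i) {
    const int mi = m[i];
    cumd[0] = 0.0;
    for (int h = 1; h <= mi; ++h) cumd[h] = cumd[h - 1] + delta(i, h - 1);
    for (int p = 0; p < P; ++p) {
      const double o = off[(size_t)i * P + p];
      for (int q = 0; q < Q; ++q) {
        const double th = sigma * nodes[q];
        const double *pr = &prob[(((size_t)i * P + p) * Q + q) * H];
        const double *a = &A[(((size_t)i * P + p) * Q + q) * H];
        double M = 0.0;
        for (int h = 0; h <= mi; ++h) M += a[h];
        if (M == 0.0) continue;
        double sum_h = 0.0, sum_zb = 0.0;
        // D_h = a[h] - M * pr[h]; d z_h / d delta_r = -beta * 1[r <= h]
        double tailD = 0.0;   // running sum of D_h for h >= r (built downward)
        for (int h = mi; h >= 1; --h) {
          const double D = a[h] - M * pr[h];
          tailD += D;
          gdelta(i, h - 1) += -beta[i] * tailD;
        }
        for (int h = 0; h <= mi; ++h) {
          const double D = a[h] - M * pr[h];
          sum_h += D * h;
          sum_zb += D * (h * th - cumd[h] - h * o);
        }
        gbeta[i] += sum_zb;
        gsigma[0] += beta[i] * nodes[q] * sum_h;
        for (int k = 0; k < K; ++k)
          ggamma(i, k) += -beta[i] * sum_h * Xu(p, k);
      }
    }
  }

  return List::create(_["loglik"] = loglik, _["grad_beta"] = gbeta,
                      _["grad_delta"] = gdelta, _["grad_gamma"] = ggamma,
                      _["grad_sigma"] = gsigma[0]);
}
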