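#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Marginal-maximum-likelihood EM for the unidimensional partial credit model
// with three ordered categories (0, 1, 2), slopes fixed at 1 and the latent
// mean fixed at 0. The latent ability is integrated out on a fixed grid of
// standardized nodes z (rectangle rule with normal-density weights); the grid
// in ability units is sigma * z and is rescaled as sigma is updated.
//
// X:      N x I integer matrix of responses in {0, 1, 2}
// d0:     I x 2 matrix of starting threshold values
// z, wz:  quadrature nodes (standardized) and normalized prior weights
// sigma0: starting latent standard deviation
// est_sigma: if false, sigma is held at sigma0 (anchored runs)
// dmax:   threshold estimates are clamped to [-dmax, dmax]; items with an
//         unobserved category drift to this boundary instead of diverging

static inline void item_logp(double th, double d1, double d2,
                             double &lp0, double &lp1, double &lp2) {
  double s1 = th - d1;
  double s2 = 2.0 * th - d1 - d2;
  double m = 0.0;
  if (s1 > m) m = s1;
  if (s2 > m) m = s2;
  double lse = m + std::log(std::exp(-m) + std::exp(s1 - m) + std::exp(s2 - m));
  lp0 = -lse; lp1 = s1 - lse; lp2 = s2 - lse;
}

// fix_d:  if true the thresholds are held at d0 (anchored runs: only the
//         latent SD is estimated)
// [[Rcpp::export(name = ".pcm_em_1d")]]
List pcm_em_1d(IntegerMatrix X, NumericMatrix d0, NumericVector z,
               NumericVector wz, double sigma0, bool est_sigma,
               double tol, int maxit, double dmax, bool fix_d = false) {
  const int N = X.nrow(), I = X.ncol(), Q = z.size();
  NumericMatrix d(clone(d0));
  double sigma = sigma0;
  std::vector<double> trace;
  trace.reserve(maxit);

  std::vector<double> lp(Q * 3 * I);   // [q + Q*(x + 3*i)], contiguous in q
  std::vector<double> W(Q * N);        // posterior, [q + Q*n]
  std::vector<double> theta(Q), acc(Q);
  std::vector<double> r(Q * 3);        // expected counts for one item
  double ll_old = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= maxit; ++iter) {
    for (int q = 0; q < Q; ++q) theta[q] = sigma * z[q];
    for (int i = 0; i < I; ++i)
      for (int q = 0; q < Q; ++q)
        item_logp(theta[q], d(i, 0), d(i, 1),
                  lp[q + Q * (0 + 3 * i)], lp[q + Q * (1 + 3 * i)],
                  lp[q + Q * (2 + 3 * i)]);

    // E-step: posterior over nodes per person, marginal log-likelihood
    double ll = 0.0, ssq = 0.0;
    for (int n = 0; n < N; ++n) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int i = 0; i < I; ++i) {
        const double *col = &lp[Q * (X(n, i) + 3 * i)];
        for (int q = 0; q < Q; ++q) acc[q] += col[q];
      }
      double m = acc[0];
      for (int q = 1; q < Q; ++q) if (acc[q] > m) m = acc[q];
      double denom = 0.0;
      double *wn = &W[Q * n];
      for (int q = 0; q < Q; ++q) {
        wn[q] = wz[q] * std::exp(acc[q] - m);
        denom += wn[q];
      }
      ll += m + std::log(denom);
      for (int q = 0; q < Q; ++q) {
        wn[q] /= denom;
        ssq += wn[q] * theta[q] * theta[q];
      }
    }
    trace.push_back(ll);

    if (iter > 1 && std::fabs(ll - ll_old) < tol * std::fabs(ll)) {
      converged = true;
      break;
    }
    ll_old = ll;

    // M-step: latent SD from posterior second moment
    if (est_sigma) {
      sigma = std::sqrt(ssq / N);
      if (sigma < 1e-3) sigma = 1e-3;
    }

    // M-step: per-item Newton on the expected complete-data log-likelihood
    if (fix_d) continue;
    for (int i = 0; i < I; ++i) {
      std::fill(r.begin(), r.end(), 0.0);
      for (int n = 0; n < N; ++n) {
        double *rx = &r[Q * X(n, i)];
        const double *wn = &W[Q * n];
        for (int q = 0; q < Q; ++q) rx[q] += wn[q];
      }
      double d1 = d(i, 0), d2 = d(i, 1);
      for (int it = 0; it < 12; ++it) {
        double g1 = 0.0, g2 = 0.0, h11 = 0.0, h22 = 0.0, h12 = 0.0;
        for (int q = 0; q < Q; ++q) {
          double lp0, lp1v, lp2v;
          item_logp(theta[q], d1, d2, lp0, lp1v, lp2v);
          double p1 = std::exp(lp1v), p2 = std::exp(lp2v);
          double nq = r[q] + r[q + Q] + r[q + 2 * Q];
          double p12 = p1 + p2;
          g1 += -(r[q + Q] + r[q + 2 * Q]) + nq * p12;
          g2 += -r[q + 2 * Q] + nq * p2;
          h11 += nq * p12 * (1.0 - p12);
          h22 += nq * p2 * (1.0 - p2);
          h12 += nq * p2 * (1.0 - p12);
        }
        // Newton ascent step: delta = Info^{-1} g with Info the (positive)
        // information matrix accumulated above
        double det = h11 * h22 - h12 * h12;
        double s1, s2;
        if (det > 1e-12 && h11 > 1e-12) {
          s1 = (h22 * g1 - h12 * g2) / det;
          s2 = (h11 * g2 - h12 * g1) / det;
        } else {  // fall back to scaled gradient when information degenerates
          s1 = g1 / (h11 + 1e-6);
          s2 = g2 / (h22 + 1e-6);
        }
        if (s1 > 2.0) s1 = 2.0; if (s1 < -2.0) s1 = -2.0;
        if (s2 > 2.0) s2 = 2.0; if (s2 < -2.0) s2 = -2.0;
        d1 += s1; d2 += s2;
        if (d1 > dmax) d1 = dmax; if (d1 < -dmax) d1 = -dmax;
        if (d2 > dmax) d2 = dmax; if (d2 < -dmax) d2 = -dmax;
        if (std::fabs(s1) < 1e-8 && std::fabs(s2) < 1e-8) break;
      }
      d(i, 0) = d1; d(i, 1) = d2;
    }
  }
  if (iter > maxit) iter = maxit;

  return List::create(_["thresholds"] = d,
                      _["sigma"] = sigma,
                      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged,
                      _["n_iterations"] = iter);
}

// Expected raw score of a set of three-category items at each theta
// (test characteristic curve), vectorized over theta.
// [[Rcpp::export(name = ".pcm_tcc")]]
NumericVector pcm_tcc(NumericVector theta, NumericVector d1, NumericVector d2) {
  const int T = theta.size(), I = d1.size();
  NumericVector out(T);
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int i = 0; i < I; ++i) {
      double lp0, lp1, lp2;
      item_logp(theta[t], d1[i], d2[i], lp0, lp1, lp2);
      s += std::exp(lp1) + 2.0 * std::exp(lp2);
    }
    out[t] = s;
  }
  return out;
}
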