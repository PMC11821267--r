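#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Parameter vector layout: (gamma[0..pg-1], alpha[0..pa-1], log(phi)).
// G is the zero-model design (logit pi), A the count-model design (log lambda),
// off a fixed per-observation offset added to the count linear predictor.

// [[Rcpp::export(name = ".zinbNegLogLik")]]
double zinbNegLogLik(NumericVector par, NumericVector y,
                     NumericMatrix G, NumericMatrix A, NumericVector off) {
  const int n = y.size(), pg = G.ncol(), pa = A.ncol();
  const double lphi = par[pg + pa];
  const double phi = std::exp(lphi);
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double eg = 0.0, ea = off[i];
    for (int k = 0; k < pg; ++k) eg += G(i, k) * par[k];
    for (int k = 0; k < pa; ++k) ea += A(i, k) * par[pg + k];
    const double lam = std::exp(ea);
    const double l1mpi = -log1pexp_(eg);       // log(1 - pi)
    const double lpi = eg - log1pexp_(eg);     // log(pi)
    if (y[i] > 0.0) {
      nll -= l1mpi + R::dnbinom_mu(y[i], phi, lam, 1);
    } else {
      const double lnb0 = phi * (lphi - std::log(phi + lam));
      const double a = lpi, b = l1mpi + lnb0;
      const double m = a > b ? a : b;
      nll -= m + std::log(std::exp(a - m) + std::exp(b - m));
    }
  }
  return nll;
}

// [[Rcpp::export(name = ".zinbNegGrad")]]
NumericVector zinbNegGrad(NumericVector par, NumericVector y,
                          NumericMatrix G, NumericMatrix A, NumericVector off) {
  const int n = y.size(), pg = G.ncol(), pa = A.ncol();
  const double lphi = par[pg + pa];
  const double phi = std::exp(lphi);
  NumericVector grad(pg + pa + 1);
  for (int i = 0; i < n; ++i) {
    double eg = 0.0, ea = off[i];
    for (int k = 0; k < pg; ++k) eg += G(i, k) * par[k];
    for (int k = 0; k < pa; ++k) ea += A(i, k) * par[pg + k];
    const double lam = std::exp(ea);
    const double pi = 1.0 / (1.0 + std::exp(-eg));
    double dg, da, dp;  // d loglik / d eta_gamma, d eta_alpha, d log phi
    if (y[i] > 0.0) {
      dg = -pi;
      da = y[i] - (phi + y[i]) * lam / (phi + lam);
      dp = phi * (R::digamma(y[i] + phi) - R::digamma(phi)
                  + lphi - std::log(phi + lam)
                  + 1.0 - (phi + y[i]) / (phi + lam));
    } else {
      const double lnb0 = phi * (lphi - std::log(phi + lam));
      const double r0 = std::exp(lnb0);
      const double p0 = pi + (1.0 - pi) * r0;
      dg = pi * (1.0 - pi) * (1.0 - r0) / p0;
      da = -(1.0 - pi) * r0 * phi * lam / (phi + lam) / p0;
      dp = (1.0 - pi) * r0 * phi
           * (lphi - std::log(phi + lam) + lam / (phi + lam)) / p0;
    }
    for (int k = 0; k < pg; ++k) grad[k] -= dg * G(i, k);
    for (int k = 0; k < pa; ++k) grad[pg + k] -= da * A(i, k);
    grad[pg + pa] -= dp;
  }
  return grad;
}
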