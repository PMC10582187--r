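// Scaled forward-backward and Viterbi recursions for a Gaussian-emission
// hidden Markov model. Only the per-frame recursions live here; model
// updates (Baum-Welch M-step) stay in R.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double dnorm_(double x, double mean, double var) {
  const double inv = 1.0 / std::sqrt(2.0 * M_PI * var);
  const double z = x - mean;
  return inv * std::exp(-0.5 * z * z / var);
}

// E-step sufficient statistics for one observation sequence.
// Returns loglik, gamma (T x K), xi_sum (K x K).
// [[Rcpp::export]]
List hmm_estep_cpp(NumericVector obs, NumericVector means,
                   NumericVector vars, NumericMatrix trans,
                   NumericVector init) {
  const int T = obs.size(), K = means.size();
  NumericMatrix B(T, K), alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);
  const double tiny = 1e-300;

  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      B(t, k) = dnorm_(obs[t], means[k], vars[k]) + tiny;

  // forward with scaling
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * B(0, k); s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      alpha(t, k) = a * B(t, k);
      s += alpha(t, k);
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  // backward, same scaling
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k)
        b += trans(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * trans(j, k) * B(t + 1, k) *
                    beta(t + 1, k) / c[t + 1];

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xi_sum"] = xi);
}

// Most likely state path (1-based), log-space Viterbi.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector obs, NumericVector means,
                              NumericVector vars, NumericMatrix trans,
                              NumericVector init) {
  const int T = obs.size(), K = means.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double tiny = 1e-300;
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(init[k] + tiny) +
                  std::log(dnorm_(obs[0], means[k], vars[k]) + tiny);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + std::log(trans(j, k) + tiny);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + std::log(dnorm_(obs[t], means[k], vars[k]) + tiny);
      psi(t, k) = arg;
    }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
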