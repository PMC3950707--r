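#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state (general K, used with K = 2) Gaussian-emission HMM machinery.
// EM (Baum-Welch) with per-frame scaling; Viterbi in log space.

static inline double dnorm_one(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

// [[Rcpp::export]]
List hmm_em_cpp(NumericVector x, NumericVector mu0, NumericVector sd0,
                NumericMatrix trans0, NumericVector init0,
                int max_iter, double tol, double sd_floor, bool shared_sd) {
  const int n = x.size();
  const int K = mu0.size();
  NumericVector mu = clone(mu0), sd = clone(sd0), init = clone(init0);
  NumericMatrix trans = clone(trans0);

  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K), B(n, K);
  NumericVector scale(n);
  double loglik = R_NegInf, loglik_prev = R_NegInf;
  int iter = 0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    // emission densities (floored to avoid zeros)
    for (int t = 0; t < n; ++t)
      for (int k = 0; k < K; ++k) {
        double d = dnorm_one(x[t], mu[k], sd[k]);
        B(t, k) = d > 1e-300 ? d : 1e-300;
      }

    // forward with scaling
    double s = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * B(0, k); s += alpha(0, k); }
    scale[0] = s;
    for (int k = 0; k < K; ++k) alpha(0, k) /= s;
    for (int t = 1; t < n; ++t) {
      s = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
        a *= B(t, k);
        alpha(t, k) = a;
        s += a;
      }
      if (s <= 0) s = 1e-300;
      scale[t] = s;
      for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    }
    loglik = 0.0;
    for (int t = 0; t < n; ++t) loglik += std::log(scale[t]);

    // backward (same scaling)
    for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
    for (int t = n - 2; t >= 0; --t)
      for (int k = 0; k < K; ++k) {
        double b = 0.0;
        for (int j = 0; j < K; ++j) b += trans(k, j) * B(t + 1, j) * beta(t + 1, j);
        beta(t, k) = b / scale[t + 1];
      }

    // posteriors
    for (int t = 0; t < n; ++t) {
      double g = 0.0;
      for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
      if (g <= 0) g = 1e-300;
      for (int k = 0; k < K; ++k) gamma(t, k) /= g;
    }

    // M step: transitions
    for (int j = 0; j < K; ++j) {
      double denom = 0.0;
      NumericVector num(K);
      for (int t = 0; t < n - 1; ++t) {
        for (int k = 0; k < K; ++k) {
          double xi = alpha(t, j) * trans(j, k) * B(t + 1, k) * beta(t + 1, k) / scale[t + 1];
          num[k] += xi;
          denom += xi;
        }
      }
      if (denom > 0)
        for (int k = 0; k < K; ++k) trans(j, k) = num[k] / denom;
    }
    // M step: emissions (optionally one noise sd shared by all states --
    // detector noise does not depend on the binding state)
    double v_pool = 0.0;
    for (int k = 0; k < K; ++k) {
      double w = 0.0, m = 0.0;
      for (int t = 0; t < n; ++t) { w += gamma(t, k); m += gamma(t, k) * x[t]; }
      if (w > 0) {
        mu[k] = m / w;
        double v = 0.0;
        for (int t = 0; t < n; ++t) {
          double d = x[t] - mu[k];
          v += gamma(t, k) * d * d;
        }
        sd[k] = std::sqrt(v / w);
        v_pool += v;
      }
      if (sd[k] < sd_floor) sd[k] = sd_floor;
    }
    if (shared_sd) {
      double s_pool = std::sqrt(v_pool / n);
      if (s_pool < sd_floor) s_pool = sd_floor;
      for (int k = 0; k < K; ++k) sd[k] = s_pool;
    }
    for (int k = 0; k < K; ++k) init[k] = gamma(0, k);

    if (iter > 0 && std::fabs(loglik - loglik_prev) < tol) { converged = true; break; }
    loglik_prev = loglik;
  }

  return List::create(_["mu"] = mu, _["sd"] = sd, _["trans"] = trans,
                      _["init"] = init, _["loglik"] = loglik,
                      _["iterations"] = iter + 1, _["converged"] = converged,
                      _["gamma"] = gamma);
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector x, NumericVector mu, NumericVector sd,
                              NumericMatrix trans, NumericVector init) {
  const int n = x.size();
  const int K = mu.size();
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  NumericMatrix ltr(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      ltr(j, k) = trans(j, k) > 0 ? std::log(trans(j, k)) : -1e308;

  for (int k = 0; k < K; ++k) {
    double d = dnorm_one(x[0], mu[k], sd[k]);
    delta(0, k) = (init[k] > 0 ? std::log(init[k]) : -1e308) +
                  std::log(d > 1e-300 ? d : 1e-300);
  }
  for (int t = 1; t < n; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + ltr(j, k);
        if (v > best) { best = v; arg = j; }
      }
      double d = dnorm_one(x[t], mu[k], sd[k]);
      delta(t, k) = best + std::log(d > 1e-300 ? d : 1e-300);
      psi(t, k) = arg;
    }

  IntegerVector path(n);
  double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta(n - 1, k) > best) { best = delta(n - 1, k); path[n - 1] = k; }
  for (int t = n - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
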