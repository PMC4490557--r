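// Gaussian hidden Markov model core: scaled Baum-Welch EM and Viterbi
// decoding for one-dimensional FRET trajectories.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double gauss(double x, double m, double s) {
  double z = (x - m) / s;
  return std::exp(-0.5 * z * z) / (s * 2.5066282746310002);
}

// [[Rcpp::export(name = ".hmm_em_cpp")]]
List hmm_em_cpp(NumericVector x, NumericVector mean0, NumericVector sd0,
                NumericMatrix trans0, NumericVector init0,
                int maxIter, double tol, double sdFloor) {
  const int T = x.size();
  const int K = mean0.size();
  NumericVector mu = clone(mean0), sd = clone(sd0), init = clone(init0);
  NumericMatrix A = clone(trans0);

  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), B(T, K);
  NumericVector scale(T);
  std::vector<double> llTrace;
  llTrace.reserve(maxIter);
  double llOld = R_NegInf, ll = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < maxIter; ++iter) {
    // emission probabilities
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k)
        B(t, k) = gauss(x[t], mu[k], sd[k]) + 1e-300;

    // forward with scaling
    double c = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * B(0, k); c += alpha(0, k); }
    scale[0] = c;
    for (int k = 0; k < K; ++k) alpha(0, k) /= c;
    for (int t = 1; t < T; ++t) {
      c = 0.0;
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * A(j, k);
        alpha(t, k) = s * B(t, k);
        c += alpha(t, k);
      }
      scale[t] = c;
      for (int k = 0; k < K; ++k) alpha(t, k) /= c;
    }
    ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(scale[t]);
    llTrace.push_back(ll);

    // backward (scaled)
    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t)
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += A(k, j) * B(t + 1, j) * beta(t + 1, j);
        beta(t, k) = s / scale[t + 1];
      }

    // posteriors
    for (int t = 0; t < T; ++t) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
      for (int k = 0; k < K; ++k) gamma(t, k) /= s;
    }

    // convergence check on relative log-likelihood change
    if (iter > 0 && std::fabs(ll - llOld) <= tol * std::fabs(llOld)) {
      converged = true;
      break;
    }
    llOld = ll;

    // M step
    NumericMatrix xiSum(K, K);
    for (int t = 0; t < T - 1; ++t) {
      double denom = 0.0;
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          denom += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k);
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          xiSum(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / denom;
    }
    for (int j = 0; j < K; ++j) {
      double rs = 0.0;
      for (int k = 0; k < K; ++k) rs += xiSum(j, k);
      if (rs > 0)
        for (int k = 0; k < K; ++k) A(j, k) = xiSum(j, k) / rs;
    }
    for (int k = 0; k < K; ++k) {
      double w = 0.0, wx = 0.0;
      for (int t = 0; t < T; ++t) { w += gamma(t, k); wx += gamma(t, k) * x[t]; }
      if (w > 0) mu[k] = wx / w;
      double wv = 0.0;
      for (int t = 0; t < T; ++t) {
        double d = x[t] - mu[k];
        wv += gamma(t, k) * d * d;
      }
      sd[k] = (w > 0) ? std::sqrt(wv / w) : sd[k];
      if (sd[k] < sdFloor) sd[k] = sdFloor;
      init[k] = gamma(0, k);
    }
  }

  return List::create(
    _["mean"] = mu, _["sd"] = sd, _["trans"] = A, _["init"] = init,
    _["logLik"] = ll, _["logLikTrace"] = NumericVector(llTrace.begin(), llTrace.end()),
    _["gamma"] = gamma, _["converged"] = converged,
    _["iterations"] = iter + 1);
}

// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
IntegerVector hmm_viterbi_cpp(NumericVector x, NumericVector mu,
                              NumericVector sd, NumericMatrix A,
                              NumericVector init) {
  const int T = x.size();
  const int K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double tiny = -1e300;

  for (int k = 0; k < K; ++k)
    delta(0, k) = (init[k] > 0 ? std::log(init[k]) : tiny) +
      std::log(gauss(x[0], mu[k], sd[k]) + 1e-300);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = tiny; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + (A(j, k) > 0 ? std::log(A(j, k)) : tiny);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + std::log(gauss(x[t], mu[k], sd[k]) + 1e-300);
      psi(t, k) = arg;
    }

  IntegerVector path(T);
  double best = tiny; int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;  // 1-based state indices
}
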