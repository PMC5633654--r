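#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a K-state HMM given a T x K log-emission
// matrix, transition matrix A (rows sum to 1) and initial distribution pi.
// Returns per-site posteriors, summed expected transition counts and the
// sequence log-likelihood.
// [[Rcpp::export]]
List fb_hmm(NumericMatrix logemit, NumericMatrix A, NumericVector pi) {
  int T = logemit.nrow(), K = logemit.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector scale(T);
  // emission in linear space, per-row shifted for stability
  NumericMatrix em(T, K);
  for (int t = 0; t < T; ++t) {
    double mx = logemit(t, 0);
    for (int k = 1; k < K; ++k) if (logemit(t, k) > mx) mx = logemit(t, k);
    for (int k = 0; k < K; ++k) em(t, k) = std::exp(logemit(t, k) - mx);
    scale[t] = mx;  // reuse as the row shift for now
  }
  double loglik = 0.0;
  NumericVector c(T);
  for (int k = 0; k < K; ++k) alpha(0, k) = pi[k] * em(0, k);
  double s0 = 0; for (int k = 0; k < K; ++k) s0 += alpha(0, k);
  c[0] = s0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s0;
  for (int t = 1; t < T; ++t) {
    double st = 0;
    for (int k = 0; k < K; ++k) {
      double a = 0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= em(t, k);
      alpha(t, k) = a; st += a;
    }
    c[t] = st;
    for (int k = 0; k < K; ++k) alpha(t, k) /= st;
  }
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + scale[t];
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double b = 0;
      for (int j = 0; j < K; ++j) b += A(k, j) * em(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }
  }
  for (int t = 0; t < T; ++t) {
    double s = 0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    double denom = c[t + 1];
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * A(j, k) * em(t + 1, k) * beta(t + 1, k) / denom;
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}

// Viterbi decoding; returns 1-based state path.
// [[Rcpp::export]]
IntegerVector viterbi_hmm(NumericMatrix logemit, NumericMatrix A, NumericVector pi) {
  int T = logemit.nrow(), K = logemit.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  NumericMatrix lA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) lA(j, k) = std::log(A(j, k));
  for (int k = 0; k < K; ++k) delta(0, k) = std::log(pi[k]) + logemit(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + lA(0, k); int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + lA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logemit(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0; double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;
}
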