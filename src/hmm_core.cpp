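#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one sequence.
// logB: T x K emission log-densities, logA-free inputs: A (K x K) and
// pi0 are passed in probability space (rows of A sum to 1).
// Returns log-likelihood, gamma (T x K), summed transition expectations
// xi (K x K), and gamma at t = 1.
// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix logB, NumericMatrix A, NumericVector pi0) {
  int T = logB.nrow(), K = logB.ncol();
  NumericMatrix b(T, K);
  NumericVector mx(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logB(t, k));
    mx[t] = m;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logB(t, k) - m);
  }
  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * b(0, k); s += alpha(0, k); }
  if (s <= 0) stop("forward pass underflow at t=1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= b(t, k);
      alpha(t, k) = a; s += a;
    }
    if (s <= 0) stop("forward pass underflow");
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double v = 0.0;
      for (int j = 0; j < K; ++j) v += A(k, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, k) = v / c[t + 1];
    }
  }
  NumericMatrix gamma(T, K), xi(K, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * A(j, k) * b(t + 1, k) * beta(t + 1, k) / c[t + 1];
  }
  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + mx[t];
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding; ties broken toward the lower state index.
// Returns 0-based state indices.
// [[Rcpp::export(name = ".viterbi_core")]]
IntegerVector viterbi_core(NumericMatrix logB, NumericMatrix A,
                           NumericVector pi0) {
  int T = logB.nrow(), K = logB.ncol();
  NumericMatrix logA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = A(j, k) > 0 ? std::log(A(j, k)) : R_NegInf;
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi0[k] > 0 ? std::log(pi0[k]) : R_NegInf) + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + logA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }   // strict > keeps lowest index
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = delta(T - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
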