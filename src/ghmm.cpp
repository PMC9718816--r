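#include <Rcpp.h>
using namespace Rcpp;

// One scaled forward-backward pass for a Gaussian-emission HMM.
// Returns state posteriors (gamma), summed transition posteriors (xi)
// and the log-likelihood; the M-step stays in R.
// [[Rcpp::export]]
List cpp_ghmm_fb(NumericVector z, NumericVector mu, NumericVector sigma,
                 NumericMatrix A, NumericVector init) {
  int n = z.size(), K = mu.size();
  NumericMatrix B(n, K);
  for (int k = 0; k < K; k++)
    for (int t = 0; t < n; t++) {
      double d = R::dnorm(z[t], mu[k], sigma[k], 0);
      B(t, k) = (d < 1e-300) ? 1e-300 : d;
    }
  NumericMatrix alpha(n, K);
  NumericVector cvec(n);
  double s = 0.0;
  for (int k = 0; k < K; k++) { alpha(0, k) = init[k] * B(0, k); s += alpha(0, k); }
  cvec[0] = s;
  for (int k = 0; k < K; k++) alpha(0, k) /= s;
  for (int t = 1; t < n; t++) {
    s = 0.0;
    for (int k = 0; k < K; k++) {
      double a = 0.0;
      for (int j = 0; j < K; j++) a += alpha(t - 1, j) * A(j, k);
      a *= B(t, k);
      alpha(t, k) = a; s += a;
    }
    cvec[t] = s;
    for (int k = 0; k < K; k++) alpha(t, k) /= s;
  }
  NumericMatrix beta(n, K), gamma(n, K), xi(K, K);
  for (int k = 0; k < K; k++) beta(n - 1, k) = 1.0;
  for (int t = n - 2; t >= 0; t--) {
    for (int j = 0; j < K; j++) {
      double b = 0.0;
      for (int k = 0; k < K; k++) b += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / cvec[t + 1];
    }
  }
  for (int t = 0; t < n; t++) {
    double g = 0.0;
    for (int k = 0; k < K; k++) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; k++) gamma(t, k) /= g;
  }
  for (int t = 0; t < n - 1; t++)
    for (int j = 0; j < K; j++)
      for (int k = 0; k < K; k++)
        xi(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) /
          cvec[t + 1];
  double ll = 0.0;
  for (int t = 0; t < n; t++) ll += std::log(cvec[t]);
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}

// Viterbi decoding (log space) for the same model.
// [[Rcpp::export]]
IntegerVector cpp_ghmm_viterbi(NumericVector z, NumericVector mu,
                               NumericVector sigma, NumericMatrix A,
                               NumericVector init) {
  int n = z.size(), K = mu.size();
  NumericMatrix logB(n, K);
  for (int k = 0; k < K; k++)
    for (int t = 0; t < n; t++)
      logB(t, k) = R::dnorm(z[t], mu[k], sigma[k], 1);
  NumericMatrix logA(K, K);
  for (int j = 0; j < K; j++)
    for (int k = 0; k < K; k++) logA(j, k) = std::log(A(j, k));
  NumericVector delta(K);
  IntegerMatrix psi(n, K);
  for (int k = 0; k < K; k++) delta[k] = std::log(init[k]) + logB(0, k);
  for (int t = 1; t < n; t++) {
    NumericVector nd(K);
    for (int k = 0; k < K; k++) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; j++) {
        double v = delta[j] + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      nd[k] = best + logB(t, k);
      psi(t, k) = arg;
    }
    delta = nd;
  }
  IntegerVector path(n);
  int arg = 0; double best = R_NegInf;
  for (int k = 0; k < K; k++) if (delta[k] > best) { best = delta[k]; arg = k; }
  path[n - 1] = arg;
  for (int t = n - 2; t >= 0; t--) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < n; t++) path[t] += 1;  // 1-based states
  return path;
}
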