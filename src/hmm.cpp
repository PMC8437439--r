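#include <Rcpp.h>
using namespace Rcpp;

// Sample a discrete-state Markov chain using R's RNG so that set.seed()
// in the calling R session makes paths reproducible. States are 0-based.
// [[Rcpp::export]]
IntegerVector markov_path_cpp(NumericMatrix trans, NumericVector init, int n) {
  int K = trans.nrow();
  if (trans.ncol() != K) stop("transition matrix must be square");
  if (init.size() != K) stop("initial distribution length must match K");
  IntegerVector path(n);
  NumericMatrix cum(K, K);
  for (int i = 0; i < K; i++) {
    double s = 0.0;
    for (int j = 0; j < K; j++) { s += trans(i, j); cum(i, j) = s; }
  }
  NumericVector cinit(K);
  double s0 = 0.0;
  for (int j = 0; j < K; j++) { s0 += init[j]; cinit[j] = s0; }
  RNGScope scope;
  double u = unif_rand();
  int s = 0;
  while (s < K - 1 && u > cinit[s]) s++;
  path[0] = s;
  for (int t = 1; t < n; t++) {
    int prev = path[t - 1];
    u = unif_rand();
    s = 0;
    while (s < K - 1 && u > cum(prev, s)) s++;
    path[t] = s;
  }
  return path;
}

// Scaled forward-backward pass. `dens` is the T x K matrix of per-sample
// emission densities. Returns the log-likelihood, posterior state
// probabilities gamma (T x K) and the summed transition posteriors xi (K x K).
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix dens, NumericMatrix trans,
                          NumericVector init) {
  int T = dens.nrow(), K = dens.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  NumericVector c(T);
  double s = 0.0;
  for (int k = 0; k < K; k++) { alpha(0, k) = init[k] * dens(0, k); s += alpha(0, k); }
  if (s <= 0.0) stop("zero likelihood at the first sample");
  c[0] = s;
  for (int k = 0; k < K; k++) alpha(0, k) /= s;
  for (int t = 1; t < T; t++) {
    s = 0.0;
    for (int k = 0; k < K; k++) {
      double a = 0.0;
      for (int j = 0; j < K; j++) a += alpha(t - 1, j) * trans(j, k);
      a *= dens(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0.0) stop("zero likelihood during the forward pass");
    c[t] = s;
    for (int k = 0; k < K; k++) alpha(t, k) /= s;
  }
  double ll = 0.0;
  for (int t = 0; t < T; t++) ll += std::log(c[t]);
  for (int k = 0; k < K; k++) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; t--) {
    for (int j = 0; j < K; j++) {
      double b = 0.0;
      for (int k = 0; k < K; k++) b += trans(j, k) * dens(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }
  for (int t = 0; t < T; t++) {
    double g = 0.0;
    for (int k = 0; k < K; k++) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; k++) gamma(t, k) /= g;
  }
  for (int t = 0; t < T - 1; t++) {
    for (int j = 0; j < K; j++)
      for (int k = 0; k < K; k++)
        xi(j, k) += alpha(t, j) * trans(j, k) * dens(t + 1, k) * beta(t + 1, k) / c[t + 1];
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding in log space. Returns the 0-based MAP state path.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logdens, NumericMatrix logtrans,
                          NumericVector loginit) {
  int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; k++) delta(0, k) = loginit[k] + logdens(0, k);
  for (int t = 1; t < T; t++) {
    for (int k = 0; k < K; k++) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; j++) {
        double v = delta(t - 1, j) + logtrans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logdens(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  for (int k = 0; k < K; k++)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); path[T - 1] = k; }
  for (int t = T - 2; t >= 0; t--) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
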