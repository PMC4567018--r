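#include <Rcpp.h>
using namespace Rcpp;

// Log partial likelihood, score vector and observed information for a
// Cox model at a fixed coefficient vector, with Breslow or Efron tie
// handling. Rows must be sorted by time (ascending). Within a tied
// time, censored subjects share the risk set with the events at that
// time (censoring after events).
// [[Rcpp::export]]
List cox_deriv_cpp(NumericMatrix X, NumericVector time, IntegerVector status,
                   NumericVector beta, bool efron) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> eta(n), w(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
    w[i] = std::exp(e);
  }
  double ll = 0.0;
  NumericVector U(p);
  NumericMatrix I(p, p);
  // running risk-set sums: S0 = sum w, S1 = sum w*x, S2 = sum w*x*x'
  double S0 = 0.0;
  std::vector<double> S1(p, 0.0), S2((size_t)p * p, 0.0);
  std::vector<double> xsum(p), S1t(p), S2t((size_t)p * p), m(p);

  int i = n - 1;
  while (i >= 0) {
    const double t = time[i];
    int j = i;
    while (j >= 0 && time[j] == t) {  // subjects entering the risk set
      S0 += w[j];
      for (int a = 0; a < p; ++a) {
        const double wx = w[j] * X(j, a);
        S1[a] += wx;
        for (int b = 0; b <= a; ++b) S2[(size_t)a * p + b] += wx * X(j, b);
      }
      --j;
    }
    int d = 0;
    double S0t = 0.0, sum_eta = 0.0;
    std::fill(xsum.begin(), xsum.end(), 0.0);
    std::fill(S1t.begin(), S1t.end(), 0.0);
    std::fill(S2t.begin(), S2t.end(), 0.0);
    for (int k = j + 1; k <= i; ++k) {
      if (status[k] == 1) {
        ++d;
        S0t += w[k];
        sum_eta += eta[k];
        for (int a = 0; a < p; ++a) {
          xsum[a] += X(k, a);
          const double wx = w[k] * X(k, a);
          S1t[a] += wx;
          for (int b = 0; b <= a; ++b) S2t[(size_t)a * p + b] += wx * X(k, b);
        }
      }
    }
    if (d > 0) {
      ll += sum_eta;
      for (int a = 0; a < p; ++a) U[a] += xsum[a];
      for (int k = 0; k < d; ++k) {
        const double frac = efron ? (double)k / d : 0.0;
        const double denom = S0 - frac * S0t;
        ll -= std::log(denom);
        for (int a = 0; a < p; ++a) {
          m[a] = (S1[a] - frac * S1t[a]) / denom;
          U[a] -= m[a];
        }
        for (int a = 0; a < p; ++a)
          for (int b = 0; b <= a; ++b)
            I(a, b) += (S2[(size_t)a * p + b] - frac * S2t[(size_t)a * p + b]) / denom
                       - m[a] * m[b];
      }
    }
    i = j;
  }
  for (int a = 0; a < p; ++a)
    for (int b = a + 1; b < p; ++b) I(a, b) = I(b, a);
  return List::create(_["loglik"] = ll, _["score"] = U, _["info"] = I);
}
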