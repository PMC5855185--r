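#include <Rcpp.h>
using namespace Rcpp;

// Per-scale raw moments of g = theta1*u + theta2*u^2 for u ~ Uniform(lo, hi),
// drawn from R's RNG stream (n draws per scale, scales in column order).
// Returns a 4 x P matrix of E[g], E[g^2], E[g^3], E[g^4] sample means.
// Draws match R's runif(n, lo, hi) bit for bit, so a pure-R path under the
// same seed reproduces these moments exactly.
// [[Rcpp::export]]
NumericMatrix mc_term_moments(NumericVector theta1, NumericVector theta2,
                              double n, double lo, double hi) {
  int P = theta1.size();
  if (theta2.size() != P) stop("theta1 and theta2 must have equal length");
  long long N = (long long)n;
  if (N < 1) stop("n must be >= 1");
  double w = hi - lo;
  NumericMatrix out(4, P);
  for (int p = 0; p < P; ++p) {
    double a = theta1[p], b = theta2[p];
    double s1 = 0.0, s2 = 0.0, s3 = 0.0, s4 = 0.0;
    for (long long j = 0; j < N; ++j) {
      double u = lo + w * unif_rand();
      double g = (a + b * u) * u;
      double g2 = g * g;
      s1 += g;
      s2 += g2;
      s3 += g2 * g;
      s4 += g2 * g2;
    }
    out(0, p) = s1 / N;
    out(1, p) = s2 / N;
    out(2, p) = s3 / N;
    out(3, p) = s4 / N;
  }
  return out;
}
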