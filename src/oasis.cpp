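#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pool-adjacent-violators solver for the l1-penalized AR(1) deconvolution
//
//   min 0.5 * sum_t (c_t - y_t)^2 + lambda * sum_t s_t
//   s.t. s_t = c_t - gamma * c_{t-1} >= 0 (t >= 2), c_1 = s_1 >= 0
//
// The l1 term is absorbed into the target: sum_t s_t = sum_t mu_t c_t with
// mu_t = 1 - gamma for t < T and mu_T = 1.  Pools store the running
// weighted numerator/denominator of their optimal starting height; a pool
// whose height violates the decay constraint against its predecessor is
// merged.  Negative pools can only occur as a prefix and are clamped to
// zero at reconstruction (the c >= 0 face of the feasible set).
//
// [[Rcpp::export]]
NumericVector oasis_ar1(NumericVector y, double gamma, double lambda) {
  const int T = y.size();
  NumericVector c(T);
  if (T == 0) return c;
  std::vector<double> num(T), den(T);
  std::vector<int> start(T), len(T);
  int np = 0;
  for (int t = 0; t < T; ++t) {
    double mu = (t == T - 1) ? 1.0 : (1.0 - gamma);
    num[np] = y[t] - lambda * mu;
    den[np] = 1.0;
    start[np] = t;
    len[np] = 1;
    ++np;
    while (np > 1) {
      double g = std::pow(gamma, len[np - 2]);
      double h_prev = num[np - 2] / den[np - 2];
      double h_cur = num[np - 1] / den[np - 1];
      if (h_cur >= g * h_prev) break;
      num[np - 2] += g * num[np - 1];
      den[np - 2] += g * g * den[np - 1];
      len[np - 2] += len[np - 1];
      --np;
    }
  }
  for (int i = 0; i < np; ++i) {
    double h = num[i] / den[i];
    if (h < 0) h = 0;
    double v = h;
    for (int k = 0; k < len[i]; ++k) {
      c[start[i] + k] = v;
      v *= gamma;
    }
  }
  return c;
}
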