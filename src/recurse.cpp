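#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Core NLARI recursion on the detrended series Y:
//   Y_t = (1 + theta1) Y_{t-1} - theta1 Y_{t-2}
//         + theta2 * ( -Y_{t-k2} * exp(-Y_{t-k2}^2) ) + eps_t
// y_init supplies the presample history, oldest first; its length must be
// max(2, kappa2).  eps drives the recursion (zeros give the deterministic
// skeleton).  The stable fixed point is not globally stable, so runaway
// trajectories are a real possibility: abort as soon as |Y| passes `guard`.
// [[Rcpp::export(name = ".nlari_recurse")]]
NumericVector nlari_recurse(NumericVector eps, double theta1, double theta2,
                            int kappa2, NumericVector y_init, double guard) {
  const int n = eps.size();
  const int p = y_init.size();  // presample length, >= max(2, kappa2)
  if (kappa2 < 1) stop("kappa2 must be >= 1");
  if (p < 2 || p < kappa2) stop("y_init must have length max(2, kappa2)");
  std::vector<double> y(n + p);
  for (int i = 0; i < p; ++i) y[i] = y_init[i];
  for (int t = p; t < n + p; ++t) {
    const double y1 = y[t - 1];
    const double y2 = y[t - 2];
    const double yk = y[t - kappa2];
    const double val = (1.0 + theta1) * y1 - theta1 * y2 +
      theta2 * (-yk * std::exp(-yk * yk)) + eps[t - p];
    if (!std::isfinite(val) || std::fabs(val) > guard)
      stop("NLARI trajectory diverged at step %d (|Y| > %g)", t - p + 1, guard);
    y[t] = val;
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = y[i + p];
  return out;
}
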