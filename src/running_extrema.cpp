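#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Running min/max of x over wavelength-width pen windows, for every i.
// The window at w[i] is [s_i, e_i] with e_i = min(w[i] + tau, w[n-1]) and
// s_i = min(w[i], w[n-1] - tau), inclusive at both ends: in the interior
// it is the plain [w[i], w[i] + tau]; near the right edge it is truncated
// at the last grid point and anchored there so the pen keeps its full
// width (otherwise the final window degenerates to a single sample and
// the association measure downstream can hit its open lower bound).
// w must be strictly increasing. Monotonic-deque sliding window, O(n).
// [[Rcpp::export(name = ".running_extrema")]]
List running_extrema(NumericVector w, NumericVector x, double tau) {
  const R_xlen_t n = w.size();
  if (n == 0) stop("empty curve");
  if (x.size() != n) stop("wavelengths and values differ in length");
  if (!(tau > 0)) stop("tau must be positive");

  NumericVector lo(n), hi(n);
  std::deque<R_xlen_t> qmin, qmax;
  R_xlen_t e = -1; // last index already pushed into the deques
  const double edge_start = w[n - 1] - tau;

  for (R_xlen_t i = 0; i < n; ++i) {
    const double right = w[i] + tau;
    const double left = w[i] < edge_start ? w[i] : edge_start;
    while (e + 1 < n && w[e + 1] <= right) {
      ++e;
      while (!qmin.empty() && x[qmin.back()] >= x[e]) qmin.pop_back();
      qmin.push_back(e);
      while (!qmax.empty() && x[qmax.back()] <= x[e]) qmax.pop_back();
      qmax.push_back(e);
    }
    while (!qmin.empty() && w[qmin.front()] < left) qmin.pop_front();
    while (!qmax.empty() && w[qmax.front()] < left) qmax.pop_front();
    lo[i] = x[qmin.front()];
    hi[i] = x[qmax.front()];
  }
  return List::create(_["lower"] = lo, _["upper"] = hi);
}
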