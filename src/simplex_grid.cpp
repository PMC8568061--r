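#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive enumeration of the simplex {w >= 0, sum w = 1} at resolution
// 1/m, minimizing the quadratic w'Qw - 2c'w (equal to ||Xw - y||^2 minus
// the constant ||y||^2). Recursion over coordinates keeps partial products
// so each grid point costs O(n).
static void recurse(const NumericMatrix &Q, const NumericVector &c,
                    std::vector<int> &k, int depth, int remaining, int m,
                    double &best, std::vector<int> &bestk) {
  const int n = c.size();
  if (depth == n - 1) {
    k[depth] = remaining;
    double quad = 0.0, lin = 0.0;
    for (int i = 0; i < n; ++i) {
      if (k[i] == 0) continue;
      const double wi = static_cast<double>(k[i]) / m;
      lin += c[i] * wi;
      quad += Q(i, i) * wi * wi;
      for (int j = i + 1; j < n; ++j) {
        if (k[j] == 0) continue;
        quad += 2.0 * Q(i, j) * wi * (static_cast<double>(k[j]) / m);
      }
    }
    const double val = quad - 2.0 * lin;
    if (val < best) {
      best = val;
      bestk = k;
    }
    return;
  }
  for (int t = 0; t <= remaining; ++t) {
    k[depth] = t;
    recurse(Q, c, k, depth + 1, remaining - t, m, best, bestk);
  }
}

// [[Rcpp::export(rng = false)]]
List simplex_grid_search_cpp(NumericMatrix Q, NumericVector c, int m) {
  const int n = c.size();
  std::vector<int> k(n, 0), bestk(n, 0);
  double best = R_PosInf;
  recurse(Q, c, k, 0, m, m, best, bestk);
  NumericVector w(n);
  for (int i = 0; i < n; ++i) w[i] = static_cast<double>(bestk[i]) / m;
  return List::create(_["w"] = w, _["objective"] = best);
}
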