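#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Lloyd iterations for k-means with fixed initial centers.
// Assignment: nearest center by squared Euclidean distance, ties to the
// lowest center index. Empty clusters are re-seeded from the point farthest
// from its current center. Converges when the relative inertia change drops
// below tol, or after max_iter iterations. Works on a row-major copy of the
// data for cache locality.
// [[Rcpp::export(name = ".lloyd_iterate")]]
List lloyd_iterate(NumericMatrix X, NumericMatrix centers_in,
                   double tol, int max_iter) {
  const int n = X.nrow(), d = X.ncol(), k = centers_in.nrow();
  // row-major copies
  std::vector<double> x(static_cast<size_t>(n) * d);
  for (int a = 0; a < d; ++a) {
    const double* col = &X(0, a);
    for (int i = 0; i < n; ++i) x[static_cast<size_t>(i) * d + a] = col[i];
  }
  std::vector<double> cen(static_cast<size_t>(k) * d);
  for (int a = 0; a < d; ++a)
    for (int j = 0; j < k; ++j) cen[static_cast<size_t>(j) * d + a] = centers_in(j, a);

  std::vector<int> lab(n, 0), sizes(k, 0);
  std::vector<double> own(n, 0.0);
  double inertia = -1.0;

  auto assign_all = [&]() {
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* xi = &x[static_cast<size_t>(i) * d];
      double best = HUGE_VAL;
      int bj = 0;
      const double* cj = cen.data();
      for (int j = 0; j < k; ++j, cj += d) {
        double s = 0.0;
        for (int a = 0; a < d; ++a) {
          const double diff = xi[a] - cj[a];
          s += diff * diff;
        }
        if (s < best) { best = s; bj = j; }
      }
      lab[i] = bj;
      own[i] = best;
      total += best;
    }
    return total;
  };

  for (int iter = 0; iter < max_iter; ++iter) {
    const double new_inertia = assign_all();
    std::fill(sizes.begin(), sizes.end(), 0);
    for (int i = 0; i < n; ++i) sizes[lab[i]]++;
    for (int j = 0; j < k; ++j) {
      if (sizes[j] == 0) {
        int far = 0; double fd = -1.0;
        for (int i = 0; i < n; ++i) if (own[i] > fd) { fd = own[i]; far = i; }
        sizes[lab[far]]--;
        lab[far] = j;
        own[far] = 0.0;
        sizes[j] = 1;
      }
    }
    std::fill(cen.begin(), cen.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double* cj = &cen[static_cast<size_t>(lab[i]) * d];
      const double* xi = &x[static_cast<size_t>(i) * d];
      for (int a = 0; a < d; ++a) cj[a] += xi[a];
    }
    for (int j = 0; j < k; ++j)
      for (int a = 0; a < d; ++a) cen[static_cast<size_t>(j) * d + a] /= sizes[j];
    if (inertia >= 0.0 && inertia > 0.0 &&
        std::fabs(inertia - new_inertia) / inertia < tol) break;
    inertia = new_inertia;
  }

  const double final_inertia = assign_all();
  NumericMatrix centers_out(k, d);
  for (int j = 0; j < k; ++j)
    for (int a = 0; a < d; ++a) centers_out(j, a) = cen[static_cast<size_t>(j) * d + a];
  IntegerVector lab_out(n);
  for (int i = 0; i < n; ++i) lab_out[i] = lab[i] + 1;  // 1-based for R
  return List::create(_["centers"] = centers_out, _["labels"] = lab_out,
                      _["inertia"] = final_inertia);
}
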