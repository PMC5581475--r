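#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Dual coordinate descent for the L2-regularized hinge-loss minimizer
//   min_w 0.5*||w||^2 + C * sum_i max(0, 1 - w.x_i)
// over difference vectors x_i (all implicit labels +1): the pairwise
// ranking-SVM primal after the constraints are rearranged into a
// classification problem.  Dual: min 0.5*a'Qa - 1'a, 0 <= a_i <= C, with
// w = sum a_i x_i.  Standard projected-gradient sweeps; the visiting order
// is re-shuffled every epoch with a fixed-seed xorshift generator, so runs
// are deterministic but convergence is far faster than a fixed order.

// [[Rcpp::export]]
List cpp_rank_svm(NumericMatrix X, double C, double tol, int max_iter) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  uint64_t rs = 0x2545F4914F6CDD1DULL;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  double maxpg = R_PosInf;
  int epoch = 0;
  for (; epoch < max_iter; ++epoch) {
    for (int k = n - 1; k > 0; --k) {
      rs ^= rs >> 12; rs ^= rs << 25; rs ^= rs >> 27;
      int j = static_cast<int>((rs * 0x9E3779B97F4A7C15ULL) %
                               static_cast<uint64_t>(k + 1));
      std::swap(order[k], order[j]);
    }
    maxpg = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      if (qii[i] <= 0.0) continue;
      double g = -1.0;
      for (int j = 0; j < d; ++j) g += w[j] * X(i, j);
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= C) pg = std::max(g, 0.0);
      if (std::fabs(pg) > maxpg) maxpg = std::fabs(pg);
      if (pg == 0.0) continue;
      double anew = std::min(std::max(alpha[i] - g / qii[i], 0.0), C);
      double delta = anew - alpha[i];
      if (delta != 0.0) {
        for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
        alpha[i] = anew;
      }
    }
    if (maxpg < tol) break;
  }
  double obj = 0.0;
  for (int j = 0; j < d; ++j) obj += 0.5 * w[j] * w[j];
  for (int i = 0; i < n; ++i) {
    double m = 1.0;
    for (int j = 0; j < d; ++j) m -= w[j] * X(i, j);
    if (m > 0.0) obj += C * m;
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["iterations"] = epoch + 1,
                      _["converged"] = (maxpg < tol),
                      _["max_violation"] = maxpg,
                      _["objective"] = obj);
}
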