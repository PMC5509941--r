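#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM:
//   min_w 0.5 * w'w + C * sum_i max(0, 1 - y_i w'x_i)
// solved in the dual (0 <= alpha_i <= C). Deterministic: coordinates are
// visited in fixed cyclic order. Expects the bias, if wanted, as an
// appended constant feature column.
// [[Rcpp::export]]
NumericVector svm_dcd_fit(const NumericMatrix& X, const NumericVector& y,
                          double C, int max_passes = 1000, double tol = 1e-6) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> alpha(n, 0.0), w(p, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) { double v = X(i, j); s += v * v; }
    qii[i] = s;
  }
  for (int pass = 0; pass < max_passes; ++pass) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] <= 0.0) continue;
      double wx = 0.0;
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;           // gradient of dual wrt alpha_i
      double PG = G;                        // projected gradient
      if (alpha[i] <= 0.0) PG = std::min(G, 0.0);
      else if (alpha[i] >= C) PG = std::max(G, 0.0);
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (std::fabs(PG) > 1e-14) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - G / qii[i], 0.0), C);
        alpha[i] = a_new;
        double d = (a_new - a_old) * y[i];
        if (d != 0.0) for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
      }
    }
    if (max_viol < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
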