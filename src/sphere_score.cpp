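#include <Rcpp.h>
using namespace Rcpp;

// Per-sphere sums of correlation-error probabilities. For every sphere
// (member column set) and every test row, computes the Pearson correlation
// between predicted (P) and observed (O) patterns over the member voxels and
// accumulates 1 - p, where p is the two-sided t-test probability of |r|
// (n - 2 df). Degenerate (constant) patterns contribute 0.
// [[Rcpp::export]]
NumericVector sphere_score_sums(const NumericMatrix& P, const NumericMatrix& O,
                                const List& members) {
  const int n_te = P.nrow();
  const int n_sph = members.size();
  NumericVector out(n_sph);
  std::vector<double> sp(n_te), sp2(n_te), so(n_te), so2(n_te), spo(n_te);
  for (int s = 0; s < n_sph; ++s) {
    IntegerVector m = members[s];
    const int nm = m.size();
    if (nm < 3) { out[s] = 0.0; continue; }
    std::fill(sp.begin(), sp.end(), 0.0);
    std::fill(sp2.begin(), sp2.end(), 0.0);
    std::fill(so.begin(), so.end(), 0.0);
    std::fill(so2.begin(), so2.end(), 0.0);
    std::fill(spo.begin(), spo.end(), 0.0);
    for (int j = 0; j < nm; ++j) {
      const int c = m[j] - 1;
      const double* pc = &P(0, c);
      const double* oc = &O(0, c);
      for (int i = 0; i < n_te; ++i) {
        const double pv = pc[i], ov = oc[i];
        sp[i] += pv; sp2[i] += pv * pv;
        so[i] += ov; so2[i] += ov * ov;
        spo[i] += pv * ov;
      }
    }
    double acc = 0.0;
    for (int i = 0; i < n_te; ++i) {
      const double vp = sp2[i] - sp[i] * sp[i] / nm;
      const double vo = so2[i] - so[i] * so[i] / nm;
      const double cv = spo[i] - sp[i] * so[i] / nm;
      if (vp <= 1e-20 || vo <= 1e-20) continue;   // degenerate: score 0
      double r = cv / std::sqrt(vp * vo);
      if (r > 1.0) r = 1.0; else if (r < -1.0) r = -1.0;
      double r2 = r * r;
      if (r2 > 1.0 - 1e-15) r2 = 1.0 - 1e-15;
      const double t = std::fabs(r) * std::sqrt((nm - 2) / (1.0 - r2));
      const double p = 2.0 * R::pt(-t, nm - 2, 1, 0);
      acc += 1.0 - p;
    }
    out[s] = acc;
  }
  return out;
}
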