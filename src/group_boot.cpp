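#include <Rcpp.h>
using namespace Rcpp;

// Accumulate subject-wise bootstrap group means: for each bootstrap sample b
// (row of `rows`), average map rows[b, s] of subject s across subjects.
// [[Rcpp::export]]
NumericMatrix boot_group_means(const List& maps, const IntegerMatrix& rows) {
  const int B = rows.nrow(), S = rows.ncol();
  const NumericMatrix first = maps[0];
  const int C = first.ncol();
  NumericMatrix out(B, C);
  for (int s = 0; s < S; ++s) {
    const NumericMatrix m = maps[s];
    for (int c = 0; c < C; ++c) {
      const double* col = &m(0, c);
      double* ocol = &out(0, c);
      for (int b = 0; b < B; ++b) ocol[b] += col[rows(b, s) - 1];
    }
  }
  for (int i = 0; i < B * C; ++i) out[i] /= S;
  return out;
}

// For each bootstrap row, threshold the null group-mean map and return the
// maximum face-connected cluster size after nearest-center fill expansion
// (fill_count[c] = number of volume voxels assigned to center c; adjacency
// is evaluated on the center lattice via `center_key`, the centers' linear
// voxel keys, with `step` the lattice spacing).
// [[Rcpp::export]]
IntegerVector boot_null_max_cluster(const NumericMatrix& boot,
                                    const NumericVector& thr,
                                    const IntegerMatrix& coords,
                                    const IntegerVector& dims,
                                    const IntegerVector& fill_count,
                                    int step) {
  const int B = boot.nrow(), C = boot.ncol();
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  // map from lattice voxel key to center index
  std::unordered_map<long long, int> key_of;
  key_of.reserve(C * 2);
  std::vector<long long> keys(C);
  for (int c = 0; c < C; ++c) {
    long long k = (long long)(coords(c, 2) - 1) * dx * dy +
      (long long)(coords(c, 1) - 1) * dx + (coords(c, 0) - 1);
    keys[c] = k;
    key_of[k] = c;
  }
  IntegerVector out(B);
  std::vector<int> supra;
  std::vector<int> stack;
  std::vector<char> visited(C, 0), is_supra(C, 0);
  for (int b = 0; b < B; ++b) {
    supra.clear();
    for (int c = 0; c < C; ++c)
      if (boot(b, c) > thr[c]) { supra.push_back(c); is_supra[c] = 1; }
    int best = 0;
    for (size_t i = 0; i < supra.size(); ++i) {
      const int c0 = supra[i];
      if (visited[c0]) continue;
      int size = 0;
      stack.clear(); stack.push_back(c0); visited[c0] = 1;
      while (!stack.empty()) {
        const int c = stack.back(); stack.pop_back();
        size += fill_count[c];
        const int cx = coords(c, 0), cy = coords(c, 1), cz = coords(c, 2);
        const int nx[6] = {cx - step, cx + step, cx, cx, cx, cx};
        const int ny[6] = {cy, cy, cy - step, cy + step, cy, cy};
        const int nz[6] = {cz, cz, cz, cz, cz - step, cz + step};
        for (int j = 0; j < 6; ++j) {
          if (nx[j] < 1 || nx[j] > dx || ny[j] < 1 || ny[j] > dy ||
              nz[j] < 1 || nz[j] > dz) continue;
          long long k = (long long)(nz[j] - 1) * dx * dy +
            (long long)(ny[j] - 1) * dx + (nx[j] - 1);
          auto it = key_of.find(k);
          if (it == key_of.end()) continue;
          const int cn = it->second;
          if (is_supra[cn] && !visited[cn]) {
            visited[cn] = 1;
            stack.push_back(cn);
          }
        }
      }
      if (size > best) best = size;
    }
    for (size_t i = 0; i < supra.size(); ++i) {
      visited[supra[i]] = 0;
      is_supra[supra[i]] = 0;
    }
    out[b] = best;
  }
  return out;
}

// k-th order statistic (1-based) of every column.
// [[Rcpp::export]]
NumericVector col_order_stat(const NumericMatrix& x, int k) {
  const int n = x.nrow(), C = x.ncol();
  if (k < 1 || k > n) stop("k out of range");
  NumericVector out(C);
  std::vector<double> buf(n);
  for (int c = 0; c < C; ++c) {
    std::copy(&x(0, c), &x(0, c) + n, buf.begin());
    std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
    out[c] = buf[k - 1];
  }
  return out;
}
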