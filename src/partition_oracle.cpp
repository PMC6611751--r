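#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive minimum of the class-count imbalance objective over all
// assignments of biopsies to k partitions. The first biopsy is pinned to
// partition 0 (relabeling symmetry). Depth-first with incremental updates.

static double cell_obj(const std::vector<double>& cell, int k, int C) {
  double worst = 0.0;
  for (int c = 0; c < C; ++c) {
    double mx = cell[c], mn = cell[c];
    for (int p = 1; p < k; ++p) {
      double v = cell[p * C + c];
      if (v > mx) mx = v;
      if (v < mn) mn = v;
    }
    if (mx - mn > worst) worst = mx - mn;
  }
  return worst;
}

static void rec(const NumericMatrix& counts, int b, int n, int k, int C,
                std::vector<double>& cell, double& best) {
  if (b == n) {
    double obj = cell_obj(cell, k, C);
    if (obj < best) best = obj;
    return;
  }
  // bound: max cell already exceeding best + min possible future min is
  // hard to compute cheaply; plain enumeration is fast enough at n <= 14
  for (int p = (b == 0 ? 0 : 0); p < (b == 0 ? 1 : k); ++p) {
    for (int c = 0; c < C; ++c) cell[p * C + c] += counts(b, c);
    rec(counts, b + 1, n, k, C, cell, best);
    for (int c = 0; c < C; ++c) cell[p * C + c] -= counts(b, c);
  }
}

// [[Rcpp::export(name = "partition_oracle")]]
double partition_oracle(NumericMatrix counts, int k) {
  int n = counts.nrow(), C = counts.ncol();
  std::vector<double> cell((size_t)k * C, 0.0);
  double best = R_PosInf;
  rec(counts, 0, n, k, C, cell, best);
  return best;
}
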