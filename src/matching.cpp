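#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Greedy 1:1 nearest-neighbor matching without replacement. Treated scores
// come in processing order; control scores are pre-sorted by (score, id) so
// the first minimum of |score difference| realizes the documented tie-break
// (lower score, then lower id). Returns the 1-based position of the matched
// control for each treated unit, or 0 if the pool is exhausted.
// [[Rcpp::export]]
IntegerVector greedy_nn_cpp(NumericVector treated, NumericVector control) {
  const int nt = treated.size(), nc = control.size();
  IntegerVector out(nt);
  std::vector<bool> used(nc, false);
  int n_used = 0;
  for (int i = 0; i < nt; ++i) {
    if (n_used == nc) { out[i] = 0; continue; }
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < nc; ++j) {
      if (used[j]) continue;
      double d = std::fabs(control[j] - treated[i]);
      if (d < best) { best = d; bj = j; }
    }
    used[bj] = true;
    ++n_used;
    out[i] = bj + 1;
  }
  return out;
}

// Count of TRUE cells over a fixed offset neighborhood (disc), interior
// pixels only; margin cells (where the disc would leave the raster) get NA.
// [[Rcpp::export]]
NumericMatrix disc_count_cpp(LogicalMatrix f, IntegerVector dr,
                             IntegerVector dc, int margin) {
  const int nr = f.nrow(), nc = f.ncol(), k = dr.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int j = margin; j < nc - margin; ++j) {
    for (int i = margin; i < nr - margin; ++i) {
      int s = 0;
      for (int q = 0; q < k; ++q)
        if (f(i + dr[q], j + dc[q])) ++s;
      out(i, j) = s;
    }
  }
  return out;
}
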