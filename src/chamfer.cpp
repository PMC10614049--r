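#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chamfer distance transform on the 8-connected grid graph: orthogonal step
// = cell, diagonal step = cell*sqrt(2). Target cells start at 0. Forward and
// backward raster scans are repeated until no cell updates; on an
// unobstructed grid two scans already reach the fixed point, the loop is a
// cheap exactness guarantee.
// [[Rcpp::export]]
NumericMatrix chamfer_dt_cpp(LogicalMatrix target, double cell) {
  const int nr = target.nrow(), nc = target.ncol();
  const double orth = cell, diag = cell * std::sqrt(2.0);
  const double INF = R_PosInf;
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = target(i, j) ? 0.0 : INF;

  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 64) {
    changed = false;
    // forward scan (top-left to bottom-right), columns = x, rows = y
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) {
        double v = d(i, j);
        if (i > 0 && d(i - 1, j) + orth < v) v = d(i - 1, j) + orth;
        if (j > 0 && d(i, j - 1) + orth < v) v = d(i, j - 1) + orth;
        if (i > 0 && j > 0 && d(i - 1, j - 1) + diag < v) v = d(i - 1, j - 1) + diag;
        if (i > 0 && j < nc - 1 && d(i - 1, j + 1) + diag < v) v = d(i - 1, j + 1) + diag;
        if (v < d(i, j)) { d(i, j) = v; changed = true; }
      }
    }
    // backward scan
    for (int i = nr - 1; i >= 0; --i) {
      for (int j = nc - 1; j >= 0; --j) {
        double v = d(i, j);
        if (i < nr - 1 && d(i + 1, j) + orth < v) v = d(i + 1, j) + orth;
        if (j < nc - 1 && d(i, j + 1) + orth < v) v = d(i, j + 1) + orth;
        if (i < nr - 1 && j < nc - 1 && d(i + 1, j + 1) + diag < v) v = d(i + 1, j + 1) + diag;
        if (i < nr - 1 && j > 0 && d(i + 1, j - 1) + diag < v) v = d(i + 1, j - 1) + diag;
        if (v < d(i, j)) { d(i, j) = v; changed = true; }
      }
    }
  }
  return d;
}
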