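#include <Rcpp.h>
using namespace Rcpp;

// Greedy nearest-neighbour chaining of a quasi-one-dimensional point set.
// Starting from `start` (0-based), repeatedly steps to the nearest unvisited
// point as long as it lies within `tol`; stops when none is reachable.
// Returns the visiting order (0-based) and the number of unreached points.
// [[Rcpp::export]]
List chain_nearest_cpp(NumericMatrix pts, int start, double tol) {
  const int n = pts.nrow();
  if (start < 0 || start >= n) stop("start index out of range");
  std::vector<bool> used(n, false);
  IntegerVector order(n);
  const double tol2 = tol * tol;
  int cur = start, len = 0;
  used[cur] = true;
  order[len++] = cur;
  while (len < n) {
    double best = R_PosInf;
    int bi = -1;
    const double cx = pts(cur, 0), cy = pts(cur, 1);
    for (int i = 0; i < n; ++i) {
      if (used[i]) continue;
      const double dx = pts(i, 0) - cx, dy = pts(i, 1) - cy;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bi = i; }
    }
    if (bi < 0 || best > tol2) break;
    used[bi] = true;
    cur = bi;
    order[len++] = bi;
  }
  return List::create(_["order"] = order[Range(0, len - 1)],
                      _["leftover"] = n - len);
}
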