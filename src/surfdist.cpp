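// Surface extraction and nearest-surface distances for mask comparison
// metrics.  A surface voxel is a positive voxel with at least one
// face-adjacent (6-connectivity) background or out-of-bounds neighbour.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_surface_mask")]]
LogicalVector cpp_surface_mask(LogicalVector mask, IntegerVector dim) {
  int R = dim[0], C = dim[1], S = dim[2];
  long n = (long)R * C * S;
  LogicalVector out(n);
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (long i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int r = (int)(i % R), c = (int)((i / R) % C), s = (int)(i / ((long)R * C));
    for (int k = 0; k < 6; ++k) {
      int rr = r + d6[k][0], cc = c + d6[k][1], ss = s + d6[k][2];
      if (rr < 0 || rr >= R || cc < 0 || cc >= C || ss < 0 || ss >= S ||
          !mask[rr + (long)R * (cc + (long)C * ss)]) {
        out[i] = true;
        break;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// For every point in A (n x 3, mm), the Euclidean distance to the nearest
// point in B (m x 3, mm).  Points are pre-sorted by the caller on the first
// coordinate so the scan can terminate early once the running best beats the
// remaining axial separation.
// [[Rcpp::export(name = ".cpp_nearest_distances")]]
NumericVector cpp_nearest_distances(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    // locate ax in B's sorted first coordinate
    int lo = 0, hi = m;
    while (lo < hi) { int mid = (lo + hi) / 2; if (B(mid, 0) < ax) lo = mid + 1; else hi = mid; }
    double best = R_PosInf;
    for (int up = lo, down = lo - 1; up < m || down >= 0;) {
      bool take_up;
      if (up >= m) take_up = false;
      else if (down < 0) take_up = true;
      else take_up = (B(up, 0) - ax) <= (ax - B(down, 0));
      int j = take_up ? up : down;
      double dx = B(j, 0) - ax;
      if (dx * dx > best) { if (take_up) up = m; else down = -1; continue; }
      double dy = B(j, 1) - ay, dz = B(j, 2) - az;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
      if (take_up) ++up; else --down;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
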