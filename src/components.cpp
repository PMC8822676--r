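// 3D connected-component labelling (26-connectivity) via breadth-first
// search over the voxel grid.  Arrays are column-major (row, col, slice).
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Returns a list: label array (0 = background) plus per-component size,
// minimum slice index and minimum row index (1-based, for tie-breaking).
// [[Rcpp::export(name = ".cpp_label_components")]]
List cpp_label_components(LogicalVector mask, IntegerVector dim) {
  int R = dim[0], C = dim[1], S = dim[2];
  long n = (long)R * C * S;
  IntegerVector labels(n);
  std::vector<int> sizes, min_slice, min_row;
  int next = 0;
  std::queue<long> q;
  for (long i = 0; i < n; ++i) {
    if (!mask[i] || labels[i]) continue;
    ++next;
    sizes.push_back(0);
    min_slice.push_back(S);
    min_row.push_back(R);
    labels[i] = next;
    q.push(i);
    while (!q.empty()) {
      long v = q.front(); q.pop();
      int r = (int)(v % R), c = (int)((v / R) % C), s = (int)(v / ((long)R * C));
      sizes[next - 1]++;
      if (s < min_slice[next - 1]) min_slice[next - 1] = s;
      if (r < min_row[next - 1]) min_row[next - 1] = r;
      for (int ds = -1; ds <= 1; ++ds) {
        int ss = s + ds; if (ss < 0 || ss >= S) continue;
        for (int dc = -1; dc <= 1; ++dc) {
          int cc = c + dc; if (cc < 0 || cc >= C) continue;
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc && !ds) continue;
            int rr = r + dr; if (rr < 0 || rr >= R) continue;
            long w = rr + (long)R * (cc + (long)C * ss);
            if (mask[w] && !labels[w]) { labels[w] = next; q.push(w); }
          }
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return List::create(_["labels"] = labels,
                      _["size"] = wrap(sizes),
                      _["min_slice"] = wrap(min_slice),
                      _["min_row"] = wrap(min_row));
}
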