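#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// iterative union-find with path compression
static int uf_find(std::vector<int>& parent, int x) {
  int root = x;
  while (parent[root] != root) root = parent[root];
  while (parent[x] != root) { int nxt = parent[x]; parent[x] = root; x = nxt; }
  return root;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labeling. Labels 1..K are assigned in
// raster-scan (row-major) order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix prov(h, w);           // provisional labels, 0 = background
  std::vector<int> parent(1, 0);      // parent[0] unused
  int next_label = 1;

  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (!mask(i, j)) continue;
      int best = 0;
      int cand[4][2] = { {i, j - 1}, {i - 1, j}, {i - 1, j - 1}, {i - 1, j + 1} };
      int ncand = (connectivity == 8) ? 4 : 2;
      for (int c = 0; c < ncand; ++c) {
        int ci = cand[c][0], cj = cand[c][1];
        if (ci < 0 || cj < 0 || cj >= w) continue;
        int lb = prov(ci, cj);
        if (lb == 0) continue;
        if (best == 0) best = lb;
        else uf_union(parent, best, lb);
      }
      if (best == 0) {
        parent.push_back(next_label);
        prov(i, j) = next_label++;
      } else {
        prov(i, j) = best;
      }
    }
  }

  // compact roots to 1..K in raster order of first occurrence
  std::vector<int> compact(parent.size(), 0);
  IntegerMatrix out(h, w);
  int k = 0;
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      int lb = prov(i, j);
      if (lb == 0) continue;
      int root = uf_find(parent, lb);
      if (compact[root] == 0) compact[root] = ++k;
      out(i, j) = compact[root];
    }
  }
  return out;
}
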