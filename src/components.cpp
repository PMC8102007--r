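#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find connected-component labelling of a binary mask.
// 8-connectivity; foreground is any value > 0. Labels are 1..n in
// first-encounter (column-major) order after relabelling.

static int find_root(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;

  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) <= 0) continue;
      // previously visited 8-neighbours in column-major order:
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      int neigh[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      int lmin = 0;
      for (int k = 0; k < 4; ++k) {
        int ni = neigh[k][0], nj = neigh[k][1];
        if (ni < 0 || ni >= H || nj < 0) continue;
        int l = lab(ni, nj);
        if (l > 0) {
          if (lmin == 0) lmin = l;
          else unite(parent, lmin, l);
        }
      }
      if (lmin == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = lmin;
      }
    }
  }

  // second pass: resolve roots and compact label ids
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find_root(parent, l);
      if (remap[r] == 0) remap[r] = ++out;
      lab(i, j) = remap[r];
    }
  return lab;
}
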