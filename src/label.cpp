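// Two-pass union-find connected-component labeling with selectable
// 4- or 8-connectivity. Labels are renumbered 1..n in order of first
// appearance in column-major scan; 0 stays background.

#include <Rcpp.h>
#include <vector>

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a != b) parent[std::max(a, b)] = std::min(a, b);
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix cb_label(const Rcpp::LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  int next = 1;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      int up = (i > 0 && mask(i - 1, j)) ? lab(i - 1, j) : 0;
      int left = (j > 0 && mask(i, j - 1)) ? lab(i, j - 1) : 0;
      int dul = 0, dll = 0;
      if (connectivity == 8) {
        dul = (i > 0 && j > 0 && mask(i - 1, j - 1)) ? lab(i - 1, j - 1) : 0;
        dll = (i < H - 1 && j > 0 && mask(i + 1, j - 1)) ? lab(i + 1, j - 1) : 0;
      }
      int cur = 0;
      for (int nb : {up, left, dul, dll}) {
        if (nb == 0) continue;
        cur = (cur == 0) ? nb : std::min(cur, nb);
      }
      if (cur == 0) {
        cur = next++;
        parent.push_back(cur);
      } else {
        for (int nb : {up, left, dul, dll})
          if (nb != 0) uf_union(parent, cur, nb);
      }
      lab(i, j) = cur;
    }
  }
  // Resolve and renumber by first appearance (column-major).
  std::vector<int> remap(next, 0);
  int n = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int v = lab(i, j);
      if (v == 0) continue;
      int r = uf_find(parent, v);
      if (remap[r] == 0) remap[r] = ++n;
      lab(i, j) = remap[r];
    }
  }
  return lab;
}
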