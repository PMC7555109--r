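#include <Rcpp.h>
using namespace Rcpp;

// Two-pass 8-connected component labeling with union-find.
// Input: logical matrix (TRUE = foreground). Output: integer matrix,
// labels 1..n in order of first appearance (column-major scan).
static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  int next = 0;
  // first pass, column-major; neighbours already visited relative to (r,c):
  // (r-1,c), (r-1,c-1), (r,c-1), (r+1,c-1)
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      int nb[4];
      int k = 0;
      if (r > 0 && mask(r - 1, c)) nb[k++] = lab(r - 1, c);
      if (c > 0) {
        if (r > 0 && mask(r - 1, c - 1)) nb[k++] = lab(r - 1, c - 1);
        if (mask(r, c - 1)) nb[k++] = lab(r, c - 1);
        if (r + 1 < H && mask(r + 1, c - 1)) nb[k++] = lab(r + 1, c - 1);
      }
      if (k == 0) {
        ++next;
        parent.push_back(next);
        lab(r, c) = next;
      } else {
        int m = nb[0];
        for (int i = 1; i < k; ++i) if (nb[i] < m) m = nb[i];
        lab(r, c) = m;
        int rm = find_root(parent, m);
        for (int i = 0; i < k; ++i) {
          int ri = find_root(parent, nb[i]);
          if (ri != rm) parent[ri] = rm;
        }
      }
    }
  }
  // second pass: resolve + renumber consecutively in scan order
  std::vector<int> newlab(next + 1, 0);
  int n_obj = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!lab(r, c)) continue;
      int root = find_root(parent, lab(r, c));
      if (!newlab[root]) newlab[root] = ++n_obj;
      lab(r, c) = newlab[root];
    }
  }
  return lab;
}

// Zhang-Suen binary thinning to a 1-px skeleton.
// [[Rcpp::export(name = ".thin_cpp")]]
LogicalMatrix thin_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix img(clone(mask));
  std::vector<std::pair<int,int> > kill;
  bool changed = true;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img(r, c) ? 1 : 0;
  };
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (!img(r, c)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
              p5 = at(r + 1, c + 1), p6 = at(r + 1, c), p7 = at(r + 1, c - 1),
              p8 = at(r, c - 1), p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        img(kill[i].first, kill[i].second) = FALSE;
    }
  }
  return img;
}

// Exact nearest-seed Euclidean (Voronoi) tessellation.
// seeds given as 1-based (row, col); ties broken by lower seed index.
// [[Rcpp::export(name = ".voronoi_cpp")]]
IntegerMatrix voronoi_cpp(int H, int W, IntegerVector seed_row, IntegerVector seed_col) {
  int n = seed_row.size();
  IntegerMatrix lab(H, W);
  if (n == 0) return lab;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double best = R_PosInf;
      int who = 1;
      for (int s = 0; s < n; ++s) {
        double dr = (double)(r + 1) - seed_row[s];
        double dc = (double)(c + 1) - seed_col[s];
        double d = dr * dr + dc * dc;
        if (d < best) { best = d; who = s + 1; }
      }
      lab(r, c) = who;
    }
  }
  return lab;
}
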