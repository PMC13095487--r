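#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Guo-Hall thinning. Input: integer matrix (0 background, nonzero
// foreground). Output: logical matrix of the 1-px-wide skeleton.
// Endpoints (pixels with a single neighbour) are never removed (the
// neighbour-count condition requires N >= 2), so line ends are preserved.
// [[Rcpp::export]]
LogicalMatrix thin_guo_hall(const IntegerMatrix &mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) img(i, j) = mask(i, j) != 0;

  // neighbour order p2..p9 clockwise starting north (row-1, col)
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};

  std::vector<std::pair<int, int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img(i, j)) continue;
          int p[8];
          for (int k = 0; k < 8; ++k) {
            int r = i + dr[k], c = j + dc[k];
            p[k] = (r >= 0 && r < nr && c >= 0 && c < nc && img(r, c)) ? 1 : 0;
          }
          // p[0]=p2 N, p[1]=p3 NE, p[2]=p4 E, p[3]=p5 SE,
          // p[4]=p6 S, p[5]=p7 SW, p[6]=p8 W, p[7]=p9 NW
          int C = ((!p[0]) & (p[1] | p[2])) + ((!p[2]) & (p[3] | p[4])) +
                  ((!p[4]) & (p[5] | p[6])) + ((!p[6]) & (p[7] | p[0]));
          int N1 = (p[7] | p[0]) + (p[1] | p[2]) + (p[3] | p[4]) +
                   (p[5] | p[6]);
          int N2 = (p[0] | p[1]) + (p[2] | p[3]) + (p[4] | p[5]) +
                   (p[6] | p[7]);
          int N = N1 < N2 ? N1 : N2;
          int m = (sub == 0) ? ((p[4] | p[5] | (!p[7])) & p[6])
                             : ((p[0] | p[1] | (!p[3])) & p[2]);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        img(kill[k].first, kill[k].second) = false;
    }
  }
  // staircase-corner pruning: a pixel with exactly two neighbours, both
  // 4-adjacent to it and diagonal to each other, is the redundant corner
  // of a staircase; removal leaves the direct diagonal step. Line tips
  // (one neighbour, or a diagonal neighbour pair) are never touched, so
  // the skeleton keeps its full extent.
  bool pruned = true;
  while (pruned) {
    pruned = false;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!img(i, j)) continue;
        int nrn = 0, ri[3], ci[3];
        bool more = false;
        for (int k = 0; k < 8; ++k) {
          int r = i + dr[k], c = j + dc[k];
          if (r >= 0 && r < nr && c >= 0 && c < nc && img(r, c)) {
            if (nrn < 2) { ri[nrn] = r; ci[nrn] = c; }
            if (++nrn > 2) { more = true; break; }
          }
        }
        if (more || nrn != 2) continue;
        bool four0 = (ri[0] == i) != (ci[0] == j);
        bool four1 = (ri[1] == i) != (ci[1] == j);
        bool diag = std::abs(ri[0] - ri[1]) == 1 &&
                    std::abs(ci[0] - ci[1]) == 1;
        if (four0 && four1 && diag) {
          img(i, j) = false;
          pruned = true;
        }
      }
    }
  }
  return img;
}

// Connected-component labeling (BFS). connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components(const LogicalMatrix &mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nb = (connectivity == 8) ? 8 : 4;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::queue<std::pair<int, int> > q;
  // column-major scan gives lexicographic (col, row) label order; stable.
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> cur = q.front();
        q.pop();
        for (int k = 0; k < nb; ++k) {
          int r = cur.first + dr8[k], c = cur.second + dc8[k];
          if (r >= 0 && r < nr && c >= 0 && c < nc && mask(r, c) &&
              !lab(r, c)) {
            lab(r, c) = next;
            q.push(std::make_pair(r, c));
          }
        }
      }
    }
  }
  return lab;
}

// Count of foreground 8-neighbours for every pixel.
// [[Rcpp::export]]
IntegerMatrix neighbor_counts(const LogicalMatrix &mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int n = 0;
      for (int k = 0; k < 8; ++k) {
        int r = i + dr[k], c = j + dc[k];
        if (r >= 0 && r < nr && c >= 0 && c < nc && mask(r, c)) ++n;
      }
      out(i, j) = n;
    }
  return out;
}

// Crossing number: 0->1 transitions in the ordered 8-neighbour ring.
// [[Rcpp::export]]
IntegerMatrix crossing_numbers(const LogicalMatrix &mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int p[8];
      for (int k = 0; k < 8; ++k) {
        int r = i + dr[k], c = j + dc[k];
        p[k] = (r >= 0 && r < nr && c >= 0 && c < nc && mask(r, c)) ? 1 : 0;
      }
      int t = 0;
      for (int k = 0; k < 8; ++k)
        if (p[k] == 0 && p[(k + 1) % 8] == 1) ++t;
      out(i, j) = t;
    }
  return out;
}
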