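#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// 8-connected neighbour offsets (row, col)
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Minimax flood level from a seed region.
//
// For every pixel p the returned value is the smallest intensity ceiling L
// such that p is 8-connected to the seed through pixels (p included, seed
// excluded) of intensity <= L. Seed pixels get -Inf: they belong to the
// flooded region at every level. Equivalently, flood(img, seed) at level L
// is { p : out[p] <= L }, which is what level-by-level watershed flooding
// from the seed produces.
//
// Dijkstra on the pixel grid with path cost = max intensity along the path.
// [[Rcpp::export]]
NumericMatrix cpp_flood_levels(NumericMatrix img, LogicalMatrix seed) {
  const int nr = img.nrow(), nc = img.ncol();
  if (seed.nrow() != nr || seed.ncol() != nc)
    stop("seed dimensions must match image dimensions");

  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), R_PosInf);
  std::vector<bool> done((size_t)nr * nc, false);

  typedef std::pair<double, int> Node; // (level, linear index col-major)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seed(i, j)) {
        out(i, j) = R_NegInf;
        pq.push(Node(R_NegInf, j * nr + i));
      }
  if (pq.empty()) stop("seed is empty");

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    int idx = top.second;
    if (done[idx]) continue;
    done[idx] = true;
    int i = idx % nr, j = idx / nr;
    double lvl = top.first;
    for (int k = 0; k < 8; ++k) {
      int ni = i + DR[k], nj = j + DC[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (done[(size_t)nj * nr + ni]) continue;
      double cand = std::max(lvl, img(ni, nj));
      if (cand < out(ni, nj)) {
        out(ni, nj) = cand;
        pq.push(Node(cand, nj * nr + ni));
      }
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask.
// Labels are positive integers in raster-scan (column-major) discovery
// order; background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc); // zero-initialised
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(j * nr + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int ni = ci + DR[k], nj = cj + DC[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(nj * nr + ni);
          }
        }
      }
    }
  return lab;
}
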