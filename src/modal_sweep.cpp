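#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Watershed-style modal clustering sweep over a square density grid.
//
// Grid points are visited in descending density (the order is supplied,
// ties already broken by (row, col)). Above the noise floor, a point whose
// four von Neumann neighbours contain no cluster founds a new cluster (a
// local mode); one adjacent cluster joins it; two or more distinct
// clusters make it a boundary point (-1). Classified points mark seven of
// their eight neighbours as contiguous, omitting one diagonal cycled by a
// modulo-4 counter so the marking stays roughly radially symmetric.
// Below-floor points are then classified outward in contiguity layers,
// joining the nearest significant cluster (falling back to the densest
// classified 8-neighbour when no 4-neighbour has a cluster).
//
// Returns labels (>=1 cluster, -1 boundary, 0 only if no cluster could be
// founded), 1-based mode indices per cluster, and a widen flag raised as
// soon as the cluster count exceeds max_clusters.
// [[Rcpp::export(name = ".modal_sweep")]]
List modal_sweep(NumericVector density, int G, double floor_,
                 IntegerVector ord, int max_clusters) {
  const int NP = G * G;
  std::vector<int> lab(NP, 0);
  std::vector<char> contig(NP, 0);
  std::vector<int> modes;
  int K = 0;
  int diag_counter = 0;
  // neighbour offsets; grid stored column-major, index = r + c*G
  auto inb = [&](int r, int c) { return r >= 0 && r < G && c >= 0 && c < G; };

  // diagonal order NE, SE, SW, NW for the modulo-4 omission
  const int dr8[8] = { -1, 1, 0, 0, -1, 1, 1, -1 };
  const int dc8[8] = { 0, 0, -1, 1, 1, 1, -1, -1 };

  auto mark_contig = [&](int p) {
    int r = p % G, c = p / G;
    int omit = 4 + (diag_counter++ % 4);  // index into dr8/dc8 diagonals
    for (int t = 0; t < 8; ++t) {
      if (t == omit) continue;
      int rr = r + dr8[t], cc = c + dc8[t];
      if (inb(rr, cc)) contig[rr + cc * G] = 1;
    }
  };

  // classify one point; phase 2 allows the 8-neighbour fallback and
  // forbids founding new clusters. Returns true when classified.
  auto classify = [&](int p, bool allow_new) -> bool {
    int r = p % G, c = p / G;
    int c1 = 0, c2 = 0;
    bool saw_boundary = false;
    for (int t = 0; t < 4; ++t) {
      int rr = r + dr8[t], cc = c + dc8[t];
      if (!inb(rr, cc)) continue;
      int l = lab[rr + cc * G];
      if (l > 0) {
        if (c1 == 0) c1 = l;
        else if (l != c1 && c2 == 0) c2 = l;
        else if (l != c1 && l != c2) c2 = l;  // >2 distinct: still boundary
      } else if (l == -1) saw_boundary = true;
    }
    if (c2 != 0) { lab[p] = -1; mark_contig(p); return true; }
    if (c1 != 0) { lab[p] = c1; mark_contig(p); return true; }
    if (allow_new) {
      if (saw_boundary) { lab[p] = -1; mark_contig(p); return true; }
      lab[p] = ++K;
      modes.push_back(p + 1);
      mark_contig(p);
      return true;
    }
    // below floor: fall back to the densest cluster-labelled 8-neighbour,
    // inheriting boundary status only when no cluster is adjacent at all
    int best = -1; double bestd = -1.0;
    for (int t = 0; t < 8; ++t) {
      int rr = r + dr8[t], cc = c + dc8[t];
      if (!inb(rr, cc)) continue;
      int q = rr + cc * G;
      if (lab[q] > 0 && density[q] > bestd) { bestd = density[q]; best = q; }
    }
    if (best >= 0) { lab[p] = lab[best]; mark_contig(p); return true; }
    if (saw_boundary) { lab[p] = -1; mark_contig(p); return true; }
    for (int t = 4; t < 8; ++t) {  // diagonal-only boundary contact
      int rr = r + dr8[t], cc = c + dc8[t];
      if (inb(rr, cc) && lab[rr + cc * G] == -1) {
        lab[p] = -1; mark_contig(p); return true;
      }
    }
    return false;
  };

  // phase 1: descending sweep down to the noise floor
  int i = 0;
  const int n_ord = ord.size();
  for (; i < n_ord; ++i) {
    int p = ord[i] - 1;
    if (density[p] < floor_) break;
    classify(p, true);
    if (K > max_clusters)
      return List::create(_["labels"] = IntegerVector(lab.begin(), lab.end()),
                          _["modes"] = IntegerVector(modes.begin(), modes.end()),
                          _["n_clusters"] = K, _["widen"] = true);
  }

  // phase 2: below-floor points, outward in contiguity layers
  if (K > 0) {
    std::vector<int> remaining;
    remaining.reserve(n_ord - i);
    for (int j = i; j < n_ord; ++j) remaining.push_back(ord[j] - 1);
    while (!remaining.empty()) {
      // snapshot the contiguity frontier so each pass classifies exactly
      // one layer: growth is then equidistant from the significant
      // clusters rather than racing along monotone density paths
      std::vector<char> frontier(contig);
      std::vector<int> next;
      next.reserve(remaining.size());
      bool progress = false;
      for (size_t j = 0; j < remaining.size(); ++j) {
        int p = remaining[j];
        if (!frontier[p] || !classify(p, false)) next.push_back(p);
        else progress = true;
      }
      if (!progress) break;  // unreachable points (cannot happen on a grid)
      remaining.swap(next);
    }
  }

  return List::create(_["labels"] = IntegerVector(lab.begin(), lab.end()),
                      _["modes"] = IntegerVector(modes.begin(), modes.end()),
                      _["n_clusters"] = K, _["widen"] = false);
}
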