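#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask with per-component geometry.
//
// Labels are assigned in row-major scan order (top-to-bottom, left-to-right),
// so component ids are deterministic and reflect first encounter.  Perimeter
// is the count of unit pixel edges adjacent to a non-fat or out-of-image
// pixel; it does not depend on the connectivity used for labeling.
//
// [[Rcpp::export]]
List label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc); // 0 = background
  int nlab = 0;

  // neighbour offsets (dr, dc)
  static const int dr4[] = {-1, 1, 0, 0};
  static const int dc4[] = {0, 0, -1, 1};
  static const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;

  std::vector<int> stack;
  std::vector<double> area, perim, sum_r, sum_c;
  std::vector<int> r0, c0, r1, c1;

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++nlab;
      area.push_back(0); perim.push_back(0);
      sum_r.push_back(0); sum_c.push_back(0);
      r0.push_back(r); c0.push_back(c); r1.push_back(r); c1.push_back(c);
      labels(r, c) = nlab;
      stack.clear();
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        int pos = stack.back(); stack.pop_back();
        int pr = pos / nc, pc = pos % nc;
        area[nlab - 1] += 1;
        sum_r[nlab - 1] += pr; sum_c[nlab - 1] += pc;
        if (pr < r0[nlab - 1]) r0[nlab - 1] = pr;
        if (pr > r1[nlab - 1]) r1[nlab - 1] = pr;
        if (pc < c0[nlab - 1]) c0[nlab - 1] = pc;
        if (pc > c1[nlab - 1]) c1[nlab - 1] = pc;
        // 4-neighbour exposed edges
        if (pr == 0      || !mask(pr - 1, pc)) perim[nlab - 1] += 1;
        if (pr == nr - 1 || !mask(pr + 1, pc)) perim[nlab - 1] += 1;
        if (pc == 0      || !mask(pr, pc - 1)) perim[nlab - 1] += 1;
        if (pc == nc - 1 || !mask(pr, pc + 1)) perim[nlab - 1] += 1;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && labels(qr, qc) == 0) {
            labels(qr, qc) = nlab;
            stack.push_back(qr * nc + qc);
          }
        }
      }
    }
  }

  NumericVector a(nlab), p(nlab), cr(nlab), cc(nlab);
  IntegerVector br0(nlab), bc0(nlab), br1(nlab), bc1(nlab), id(nlab);
  for (int i = 0; i < nlab; ++i) {
    id[i] = i + 1;
    a[i] = area[i]; p[i] = perim[i];
    cr[i] = sum_r[i] / area[i] + 1;  // 1-based row/col centroids for R
    cc[i] = sum_c[i] / area[i] + 1;
    br0[i] = r0[i] + 1; bc0[i] = c0[i] + 1;       // closed lower bound, 1-based
    br1[i] = r1[i] + 2; bc1[i] = c1[i] + 2;       // half-open upper bound
  }
  return List::create(
    _["labels"] = labels, _["id"] = id, _["area"] = a, _["perimeter"] = p,
    _["centroid_row"] = cr, _["centroid_col"] = cc,
    _["r0"] = br0, _["c0"] = bc0, _["r1"] = br1, _["c1"] = bc1);
}
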