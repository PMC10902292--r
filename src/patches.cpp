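#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Threshold-scanning connected-component sweep for gamma patch detection.
//
// Cells are activated in order of decreasing amplitude. Components are
// tracked with a union-find structure; when two components that already
// existed at an earlier threshold merge, their pre-merge extents are
// frozen and stored as separate patches and the merged component is
// marked tainted. The scan stops at the end of the first threshold level
// at which max_count patches are assigned to the central block (amplitude
// majority; ties go to the earlier block). Returns every frozen or live
// pristine patch with its cells, birth threshold and assigned block; the
// R wrapper does the final ranking and trimming.
// [[Rcpp::export(name = ".threshold_scan_cpp")]]
List threshold_scan_cpp(NumericMatrix mat, LogicalVector row_ok,
                        int max_count, IntegerVector block_of, int central) {
  const int nr = mat.nrow(), nc = mat.ncol();
  const int n = nr * nc;
  const double *amp = REAL(mat);

  std::vector<int> cells;
  cells.reserve(n);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int i = c * nr + r;
      if (row_ok[r] && amp[i] > 0) cells.push_back(i);
    }
  if (cells.empty()) return List::create();
  std::sort(cells.begin(), cells.end(),
            [&](int a, int b) { return amp[a] > amp[b]; });

  std::vector<int> parent(n, -1), birth(n, 0), head(n, -1), tail(n, -1),
      nxt(n, -1), sz(n, 0);
  std::vector<bool> tainted(n, false), in_pris(n, false);
  std::vector<double> bs(3 * n, 0.0);
  std::vector<int> pris;      // lazy list of pristine roots

  struct Patch { std::vector<int> cells; double thr; int block; };
  std::vector<Patch> frozen;
  int frozen_central = 0;

  auto find = [&](int i) {
    int r = i;
    while (parent[r] != r) r = parent[r];
    while (parent[i] != r) { int t = parent[i]; parent[i] = r; i = t; }
    return r;
  };
  auto winner = [&](const double *s) {
    int w = 0;
    if (s[1] > s[w]) w = 1;
    if (s[2] > s[w]) w = 2;
    return w;
  };

  size_t q = 0;
  double stop_thr = amp[cells.back()];
  bool stopped = false;
  int level = 0;

  while (q < cells.size() && !stopped) {
    ++level;
    double lvl_val = amp[cells[q]];
    // activate all cells at this amplitude level
    while (q < cells.size() && amp[cells[q]] == lvl_val) {
      int i = cells[q++];
      parent[i] = i; birth[i] = level;
      head[i] = tail[i] = i; nxt[i] = -1; sz[i] = 1;
      bs[3 * i + block_of[(i) / nr]] = amp[i];
      tainted[i] = false;
      in_pris[i] = true; pris.push_back(i);
      int r = i % nr, c = i / nr;
      int nb[4]; int nnb = 0;
      if (r > 0) nb[nnb++] = i - 1;
      if (r < nr - 1) nb[nnb++] = i + 1;
      if (c > 0) nb[nnb++] = i - nr;
      if (c < nc - 1) nb[nnb++] = i + nr;
      for (int k = 0; k < nnb; ++k) {
        int j = nb[k];
        if (parent[j] < 0) continue;
        int ra = find(i), rb = find(j);
        if (ra == rb) continue;
        bool est_a = birth[ra] < level, est_b = birth[rb] < level;
        bool taint_new;
        if (est_a && est_b) {
          int pair_[2] = {ra, rb};
          for (int t = 0; t < 2; ++t) {
            int rt = pair_[t];
            if (!tainted[rt]) {
              Patch p; p.thr = lvl_val;
              double s[3] = {0, 0, 0};
              for (int m = head[rt]; m != -1; m = nxt[m])
                if (amp[m] > lvl_val) {
                  p.cells.push_back(m);
                  s[block_of[m / nr]] += amp[m];
                }
              if (!p.cells.empty()) {
                p.block = winner(s);
                if (p.block == central) ++frozen_central;
                frozen.push_back(std::move(p));
              }
            }
          }
          taint_new = true;
        } else {
          taint_new = tainted[ra] || tainted[rb];
        }
        if (sz[ra] < sz[rb]) std::swap(ra, rb);
        parent[rb] = ra;
        nxt[tail[ra]] = head[rb];
        tail[ra] = tail[rb];
        sz[ra] += sz[rb];
        for (int b = 0; b < 3; ++b) bs[3 * ra + b] += bs[3 * rb + b];
        birth[ra] = std::min(birth[ra], birth[rb]);
        tainted[ra] = taint_new;
        in_pris[rb] = false;
        if (taint_new) in_pris[ra] = false;
      }
    }
    // level-end stopping check: central-assigned patch count
    int n_central = frozen_central;
    size_t w = 0;
    for (size_t k = 0; k < pris.size(); ++k) {
      int rt = pris[k];
      if (!in_pris[rt] || find(rt) != rt) { in_pris[rt] = false; continue; }
      pris[w++] = rt;
      if (winner(&bs[3 * rt]) == central) ++n_central;
    }
    pris.resize(w);
    if (n_central >= max_count) { stop_thr = lvl_val; stopped = true; }
  }
  if (!stopped) stop_thr = amp[cells.back()];

  List out;
  for (size_t k = 0; k < frozen.size(); ++k) {
    IntegerVector cv(frozen[k].cells.begin(), frozen[k].cells.end());
    out.push_back(List::create(_["cells"] = cv + 1,
                               _["birth_threshold"] = frozen[k].thr,
                               _["block"] = frozen[k].block));
  }
  for (size_t k = 0; k < pris.size(); ++k) {
    int rt = pris[k];
    if (!in_pris[rt] || find(rt) != rt) continue;
    std::vector<int> mm;
    for (int m = head[rt]; m != -1; m = nxt[m]) mm.push_back(m);
    IntegerVector cv(mm.begin(), mm.end());
    out.push_back(List::create(_["cells"] = cv + 1,
                               _["birth_threshold"] = stop_thr,
                               _["block"] = winner(&bs[3 * rt])));
  }
  return out;
}
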