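#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Stage-1 seed scan: walk every diagonal of the (i, j) grid and emit the
// maximal gapless runs on which the two intra-molecular distance matrices
// agree within eps over a band of width d1, i.e. for every position a of the
// run and every b in [max(0, a - d1), a):
//   |D1[i+a, i+b] - D2[j+a, j+b]| <= eps.
// A run never crosses a chain break (break1[k] marks a break between residues
// k and k+1, 0-based).  Runs shorter than lmin are dropped.  O(d1 * m1 * m2).
//
// Maximality follows from the restart rule: when extending a run [s, p-1] to
// p first fails at band offset tfail, any run containing p must start at
// s' >= p - tfail + 1; starts are therefore strictly increasing and no
// emitted run contains another.
// [[Rcpp::export]]
IntegerMatrix scan_seed_runs(NumericMatrix D1, NumericMatrix D2,
                             double eps, int d1, int lmin,
                             LogicalVector break1, LogicalVector break2) {
  const int m1 = D1.nrow(), m2 = D2.nrow();
  std::vector<int> oi, oj, ol;
  for (int c = -(m2 - 1); c <= m1 - 1; ++c) {
    const int i0 = c >= 0 ? c : 0;       // 0-based start in chain 1
    const int j0 = c >= 0 ? 0 : -c;      // 0-based start in chain 2
    const int L = std::min(m1 - i0, m2 - j0);
    if (L < lmin) continue;
    int s = 0;
    for (int p = 1; p <= L; ++p) {
      int tfail = 0;                     // 0 = extends, -1 = chain break
      if (p < L) {
        const int a1 = i0 + p, a2 = j0 + p;
        if (break1[a1 - 1] || break2[a2 - 1]) {
          tfail = -1;
        } else {
          const int tmax = std::min(d1, p - s);
          for (int t = 1; t <= tmax; ++t) {
            if (std::abs(D1(a1, a1 - t) - D2(a2, a2 - t)) > eps) {
              tfail = t;
              break;
            }
          }
        }
        if (tfail == 0) continue;
      }
      if (p - s >= lmin) {               // close maximal run [s, p-1]
        oi.push_back(i0 + s + 1);        // 1-based for R
        oj.push_back(j0 + s + 1);
        ol.push_back(p - s);
      }
      if (p == L) break;
      s = (tfail == -1) ? p : (p - tfail + 1);
    }
  }
  IntegerMatrix out(oi.size(), 3);
  for (R_xlen_t k = 0; k < (R_xlen_t)oi.size(); ++k) {
    out(k, 0) = oi[k];
    out(k, 1) = oj[k];
    out(k, 2) = ol[k];
  }
  colnames(out) = CharacterVector::create("i", "j", "l");
  return out;
}

// Square linear assignment (Jonker-Volgenant style shortest augmenting
// paths with potentials, O(n^3)).  Returns the 1-based column assigned to
// each row of the minimum-total-cost perfect assignment.  Used for
// min-distance maximum-cardinality bipartite matching: forbidden pairings
// carry a cost larger than any feasible distance sum, so minimizing total
// cost first maximizes the number of allowed pairings, then minimizes their
// distance sum.
// [[Rcpp::export]]
IntegerVector solve_assignment(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      int j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
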