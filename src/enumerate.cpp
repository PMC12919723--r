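// Depth-first enumeration of feasible mechanism matrices.
//
// Candidate rows (already satisfying the per-row predicates and the
// sign restrictions implied by the species roles) are supplied from R in
// lexicographic order; the search composes them row by row, pruning a
// partial matrix as soon as
//   * an intermediate's running column sum goes negative (a species would
//     be consumed before enough of it has been produced), or
//   * a column sum can no longer reach its target with the rows that
//     remain, given the per-column entry range and the per-row molecule
//     budgets.
// Matrices are emitted in lexicographic order of their row-index tuples,
// which (rows being lex-sorted) is lexicographic order of the matrices
// themselves.

#include <Rcpp.h>
#include <ctime>
#include <vector>

using namespace Rcpp;

namespace {

struct SearchState {
  const int *rows;        // R x N candidate rows, column-major
  int n_rows, n_cols, n_steps;
  const int *targets;     // length N
  const int *is_inter;    // length N, 0/1
  const int *col_min;     // min admissible entry per column
  const int *col_max;     // max admissible entry per column
  int max_reactant, max_product;
  double budget;          // seconds; <= 0 means unlimited
  std::clock_t t0;
  bool expired;
  long nodes;
  std::vector<int> chosen;     // row index per depth
  std::vector<int> colsum;     // running column sums
  std::vector<int> out_rows;   // flat row indices of accepted matrices
};

inline int entry(const SearchState &S, int row, int col) {
  return S.rows[row + (std::size_t)col * S.n_rows];
}

bool budget_hit(SearchState &S) {
  if (S.budget <= 0) return false;
  if ((++S.nodes & 0xFFF) != 0) return false;
  double el = double(std::clock() - S.t0) / CLOCKS_PER_SEC;
  if (el > S.budget) S.expired = true;
  return S.expired;
}

void dfs(SearchState &S, int depth, int first_lo, int first_hi,
         const int *first_idx) {
  if (S.expired) return;
  const int n = S.n_cols;
  const bool last = (depth == S.n_steps - 1);
  const int rem = S.n_steps - depth - 1;  // rows after this one
  const int lo = (depth == 0) ? first_lo : 0;
  const int hi = (depth == 0) ? first_hi : S.n_rows;
  for (int pos = lo; pos < hi; ++pos) {
    if (budget_hit(S)) return;
    const int i = (depth == 0) ? first_idx[pos] : pos;
    bool ok = true;
    for (int j = 0; j < n; ++j) {
      const int cs = S.colsum[j] + entry(S, i, j);
      if (S.is_inter[j] && cs < 0) { ok = false; break; }
      if (cs + rem * S.col_min[j] > S.targets[j] ||
          cs + rem * S.col_max[j] < S.targets[j]) { ok = false; break; }
    }
    if (ok && rem > 0) {
      // aggregate molecule budgets over the remaining rows
      int need_neg = 0, need_pos = 0;
      for (int j = 0; j < n; ++j) {
        const int d = S.targets[j] - (S.colsum[j] + entry(S, i, j));
        if (d < 0) need_neg -= d; else need_pos += d;
      }
      if (need_neg > rem * S.max_reactant || need_pos > rem * S.max_product)
        ok = false;
    }
    if (!ok) continue;
    for (int j = 0; j < n; ++j) S.colsum[j] += entry(S, i, j);
    S.chosen[depth] = i;
    if (last) {
      // column sums match exactly here (rem = 0 bounds); require every
      // intermediate column to be touched by at least one step
      bool used = true;
      for (int j = 0; j < n && used; ++j) {
        if (!S.is_inter[j]) continue;
        bool any = false;
        for (int d = 0; d < S.n_steps; ++d)
          if (entry(S, S.chosen[d], j) != 0) { any = true; break; }
        used = any;
      }
      if (used)
        S.out_rows.insert(S.out_rows.end(), S.chosen.begin(), S.chosen.end());
    } else {
      dfs(S, depth + 1, 0, 0, first_idx);
    }
    for (int j = 0; j < n; ++j) S.colsum[j] -= entry(S, i, j);
    if (S.expired) return;
  }
}

}  // namespace

extern "C" SEXP kinmech_enumerate(SEXP rowsS, SEXP targetsS, SEXP nstepsS,
                                  SEXP interS, SEXP colminS, SEXP colmaxS,
                                  SEXP maxrS, SEXP maxpS, SEXP budgetS,
                                  SEXP firstS) {
  IntegerMatrix rows(rowsS);
  IntegerVector targets(targetsS), inter(interS), colmin(colminS),
      colmax(colmaxS), first(firstS);
  SearchState S;
  S.rows = rows.begin();
  S.n_rows = rows.nrow();
  S.n_cols = rows.ncol();
  S.n_steps = as<int>(nstepsS);
  S.targets = targets.begin();
  S.is_inter = inter.begin();
  S.col_min = colmin.begin();
  S.col_max = colmax.begin();
  S.max_reactant = as<int>(maxrS);
  S.max_product = as<int>(maxpS);
  S.budget = as<double>(budgetS);
  S.t0 = std::clock();
  S.expired = false;
  S.nodes = 0;
  S.chosen.assign(S.n_steps, 0);
  S.colsum.assign(S.n_cols, 0);

  // first-row indices are 1-based from R
  std::vector<int> first0(first.size());
  for (int i = 0; i < first.size(); ++i) first0[i] = first[i] - 1;

  if (S.n_rows > 0 && first.size() > 0)
    dfs(S, 0, 0, (int)first0.size(), first0.data());

  const int n_found = (int)(S.out_rows.size() / S.n_steps);
  List mats(n_found);
  for (int m = 0; m < n_found; ++m) {
    IntegerMatrix M(S.n_steps, S.n_cols);
    for (int d = 0; d < S.n_steps; ++d) {
      const int ri = S.out_rows[(std::size_t)m * S.n_steps + d];
      for (int j = 0; j < S.n_cols; ++j) M(d, j) = entry(S, ri, j);
    }
    mats[m] = M;
  }
  return List::create(_["matrices"] = mats,
                      _["complete"] = !S.expired,
                      _["nodes"] = (double)S.nodes);
}
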