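#include <Rcpp.h>
using namespace Rcpp;

// In-place column/row writers for the preallocated population store.
// R's complex assignment into environment-held matrices duplicates the
// whole matrix; these setters mutate by reference. They are only ever
// called on store matrices freshly allocated by the engine, never on
// user-visible objects.

// [[Rcpp::export]]
void cpp_set_cols_int(IntegerMatrix m, IntegerVector cols,
                      IntegerMatrix vals) {
  int nr = m.nrow();
  if (vals.nrow() != nr) stop("row mismatch");
  for (int j = 0; j < cols.size(); ++j) {
    int c = cols[j] - 1;
    if (c < 0 || c >= m.ncol()) stop("column out of range");
    IntegerMatrix::Column src = vals(_, j);
    IntegerMatrix::Column dst = m(_, c);
    std::copy(src.begin(), src.end(), dst.begin());
  }
}

// [[Rcpp::export]]
void cpp_set_cols_num(NumericMatrix m, IntegerVector cols,
                      NumericMatrix vals) {
  int nr = m.nrow();
  if (vals.nrow() != nr) stop("row mismatch");
  for (int j = 0; j < cols.size(); ++j) {
    int c = cols[j] - 1;
    if (c < 0 || c >= m.ncol()) stop("column out of range");
    NumericMatrix::Column src = vals(_, j);
    NumericMatrix::Column dst = m(_, c);
    std::copy(src.begin(), src.end(), dst.begin());
  }
}

// [[Rcpp::export]]
void cpp_set_row_num(NumericMatrix m, int row, NumericVector vals) {
  if (row < 1 || row > m.nrow()) stop("row out of range");
  if (vals.size() != m.ncol()) stop("length mismatch");
  for (int j = 0; j < m.ncol(); ++j) m(row - 1, j) = vals[j];
}

// [[Rcpp::export]]
void cpp_set1_num(NumericVector v, int i, double val) {
  if (i < 1 || i > v.size()) stop("index out of range");
  v[i - 1] = val;
}

// Offspring genome assembly. Sexual mode: per offspring, recombine each
// parent's haplotype pair (Poisson(rrate) crossovers, cut points uniform
// without replacement among the L-1 boundaries, segments alternating, the
// first segment unchanged), then assort one recombined haplotype from each
// parent. Asexual mode: copy both haplotypes of the sole parent. Uses R's
// RNG stream (caller manages stream scoping).
static void recombine_into(const int *src, int *dst, int L, double rrate) {
  std::copy(src, src + 2 * L, dst);
  int ncross = (int) R::rpois(rrate);
  if (ncross <= 0 || L < 2) return;
  if (ncross > L - 1) ncross = L - 1;
  // distinct uniform cut points in [1, L-1]: partial Fisher-Yates over the
  // candidate boundaries (exact sampling without replacement)
  static std::vector<int> cand;
  static std::vector<int> cuts;
  if ((int) cand.size() != L - 1) cand.resize(L - 1);
  for (int i = 0; i < L - 1; ++i) cand[i] = i + 1;
  cuts.clear();
  for (int i = 0; i < ncross; ++i) {
    int j = i + (int) (unif_rand() * (L - 1 - i));
    if (j > L - 2) j = L - 2;
    std::swap(cand[i], cand[j]);
    cuts.push_back(cand[i]);
  }
  std::sort(cuts.begin(), cuts.end());
  cuts.push_back(L);
  bool swap = false;
  int pos = 0;
  for (size_t s = 0; s < cuts.size(); ++s) {
    if (swap) {
      for (int i = pos; i < cuts[s]; ++i) std::swap(dst[i], dst[L + i]);
    }
    pos = cuts[s];
    swap = !swap;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_offspring(IntegerMatrix mat, int L, IntegerVector pa,
                            IntegerVector pb, double rrate, bool sexual) {
  int k = pa.size();
  IntegerMatrix kids(2 * L, k);
  std::vector<int> ga(2 * L), gb(2 * L);
  for (int j = 0; j < k; ++j) {
    const int *colA = &mat(0, pa[j] - 1);
    if (!sexual) {
      std::copy(colA, colA + 2 * L, &kids(0, j));
      continue;
    }
    const int *colB = &mat(0, pb[j] - 1);
    recombine_into(colA, ga.data(), L, rrate);
    recombine_into(colB, gb.data(), L, rrate);
    int offa = (unif_rand() < 0.5) ? 0 : L;
    int offb = (unif_rand() < 0.5) ? 0 : L;
    std::copy(ga.data() + offa, ga.data() + offa + L, &kids(0, j));
    std::copy(gb.data() + offb, gb.data() + offb + L, &kids(L, j));
  }
  return kids;
}

// Symmetric per-bit mutation in place, exact Bernoulli(rate) per bit via
// geometric gap skipping.
// [[Rcpp::export]]
void cpp_mutate_sym(IntegerMatrix mat, NumericVector rate) {
  int m = mat.nrow();
  for (int j = 0; j < mat.ncol(); ++j) {
    double r = rate[j % rate.size()];
    if (r <= 0) continue;
    if (r >= 1) {
      for (int i = 0; i < m; ++i) mat(i, j) = 1 - mat(i, j);
      continue;
    }
    double lq = log1p(-r);
    double pos = -1.0;
    while (true) {
      pos += 1.0 + floor(log(unif_rand()) / lq);
      if (pos >= m) break;
      int i = (int) pos;
      mat(i, j) = 1 - mat(i, j);
    }
  }
}

// Move the given columns (strictly increasing) to the front, in order,
// in place. Used by store compaction.
// [[Rcpp::export]]
void cpp_move_cols_int(IntegerMatrix m, IntegerVector from) {
  int nr = m.nrow();
  for (int j = 0; j < from.size(); ++j) {
    int src = from[j] - 1;
    if (src == j) continue;
    std::copy(&m(0, src), &m(0, src) + nr, &m(0, j));
  }
}

// [[Rcpp::export]]
void cpp_move_cols_num(NumericMatrix m, IntegerVector from) {
  int nr = m.nrow();
  for (int j = 0; j < from.size(); ++j) {
    int src = from[j] - 1;
    if (src == j) continue;
    std::copy(&m(0, src), &m(0, src) + nr, &m(0, j));
  }
}
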