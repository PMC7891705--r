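#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Barcodes are passed as integer matrices (one row per barcode) with the
// 2-bit base encoding A=0, C=1, G=2, T=3.  Watson-Crick partners therefore
// satisfy a + b == 3, which the complementarity kernels rely on.

static inline int hp_row(const int *x, int l) {
  int best = 1, run = 1;
  for (int i = 1; i < l; ++i) {
    if (x[i] == x[i - 1]) {
      if (++run > best) best = run;
    } else {
      run = 1;
    }
  }
  return best;
}

// Maximum number of consecutive tandem copies of any dinucleotide unit;
// a tandem run may start at any position.  Homopolymer runs count as
// copies of the XX unit.  Minimum reported value is 1.
static inline int sr_row(const int *x, int l) {
  if (l < 2) return 1;
  int best = 1;
  for (int s = 0; s + 1 < l; ++s) {
    int u0 = x[s], u1 = x[s + 1];
    int k = 1, p = s + 2;
    while (p + 1 < l && x[p] == u0 && x[p + 1] == u1) {
      ++k;
      p += 2;
    }
    if (k > best) best = k;
  }
  return best;
}

static inline int hd_pair(const int *a, const int *b, int l) {
  int d = 0;
  for (int i = 0; i < l; ++i) d += (a[i] != b[i]);
  return d;
}

// Maximum Watson-Crick base pairs over all ungapped antiparallel offsets
// with overlap >= min_overlap.  b is traversed 3'->5' against a (5'->3'):
// position i of a is paired with position l2-1-i-o of b.
static inline int cp_pair(const int *a, int l1, const int *b, int l2,
                          int min_overlap) {
  int best = 0;
  for (int o = -(l1 - min_overlap); o <= l2 - min_overlap; ++o) {
    int lo = std::max(0, -o);
    int hi = std::min(l1 - 1, l2 - 1 - o);
    if (hi - lo + 1 < min_overlap) continue;
    int cnt = 0;
    for (int i = lo; i <= hi; ++i) cnt += (a[i] + b[l2 - 1 - i - o] == 3);
    if (cnt > best) best = cnt;
  }
  return best;
}

// Unit-cost edit distance, two-row DP.
static inline int ld_pair(const int *a, int l1, const int *b, int l2) {
  std::vector<int> prev(l2 + 1), cur(l2 + 1);
  for (int j = 0; j <= l2; ++j) prev[j] = j;
  for (int i = 1; i <= l1; ++i) {
    cur[0] = i;
    for (int j = 1; j <= l2; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
      cur[j] = std::min(sub, std::min(prev[j], cur[j - 1]) + 1);
    }
    std::swap(prev, cur);
  }
  return prev[l2];
}

static std::vector<int> flatten(const IntegerMatrix &m) {
  int n = m.nrow(), l = m.ncol();
  std::vector<int> out((size_t)n * l);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < l; ++j) out[(size_t)i * l + j] = m(i, j);
  return out;
}

// [[Rcpp::export]]
IntegerVector hp_lengths_c(IntegerMatrix m) {
  int n = m.nrow(), l = m.ncol();
  std::vector<int> x = flatten(m);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hp_row(&x[(size_t)i * l], l);
  return out;
}

// [[Rcpp::export]]
IntegerVector sr_repeats_c(IntegerMatrix m) {
  int n = m.nrow(), l = m.ncol();
  std::vector<int> x = flatten(m);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sr_row(&x[(size_t)i * l], l);
  return out;
}

// Elementwise Hamming distance between paired rows of a and b.
// [[Rcpp::export]]
IntegerVector hd_rows_c(IntegerMatrix a, IntegerMatrix b) {
  int n = a.nrow(), l = a.ncol();
  if (b.nrow() != n || b.ncol() != l) stop("row/column mismatch");
  std::vector<int> xa = flatten(a), xb = flatten(b);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = hd_pair(&xa[(size_t)i * l], &xb[(size_t)i * l], l);
  return out;
}

// Hamming distances for index pairs (ii, jj) (1-based) into the rows of m.
// [[Rcpp::export]]
IntegerVector hd_index_pairs_c(IntegerMatrix m, IntegerVector ii,
                               IntegerVector jj) {
  int l = m.ncol();
  std::vector<int> x = flatten(m);
  R_xlen_t np = ii.size();
  IntegerVector out(np);
  for (R_xlen_t p = 0; p < np; ++p)
    out[p] = hd_pair(&x[(size_t)(ii[p] - 1) * l], &x[(size_t)(jj[p] - 1) * l], l);
  return out;
}

// Complementarity for paired rows of a and b (lengths may differ).
// [[Rcpp::export]]
IntegerVector cp_rows_c(IntegerMatrix a, IntegerMatrix b, int min_overlap) {
  int n = a.nrow(), l1 = a.ncol(), l2 = b.ncol();
  if (b.nrow() != n) stop("row mismatch");
  std::vector<int> xa = flatten(a), xb = flatten(b);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cp_pair(&xa[(size_t)i * l1], l1, &xb[(size_t)i * l2], l2,
                     min_overlap);
  return out;
}

// [[Rcpp::export]]
IntegerVector cp_index_pairs_c(IntegerMatrix m, IntegerVector ii,
                               IntegerVector jj, int min_overlap) {
  int l = m.ncol();
  std::vector<int> x = flatten(m);
  R_xlen_t np = ii.size();
  IntegerVector out(np);
  for (R_xlen_t p = 0; p < np; ++p)
    out[p] = cp_pair(&x[(size_t)(ii[p] - 1) * l], l,
                     &x[(size_t)(jj[p] - 1) * l], l, min_overlap);
  return out;
}

// [[Rcpp::export]]
IntegerVector ld_rows_c(IntegerMatrix a, IntegerMatrix b) {
  int n = a.nrow(), l1 = a.ncol(), l2 = b.ncol();
  if (b.nrow() != n) stop("row mismatch");
  std::vector<int> xa = flatten(a), xb = flatten(b);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ld_pair(&xa[(size_t)i * l1], l1, &xb[(size_t)i * l2], l2);
  return out;
}

// [[Rcpp::export]]
IntegerVector ld_index_pairs_c(IntegerMatrix m, IntegerVector ii,
                               IntegerVector jj) {
  int l = m.ncol();
  std::vector<int> x = flatten(m);
  R_xlen_t np = ii.size();
  IntegerVector out(np);
  for (R_xlen_t p = 0; p < np; ++p)
    out[p] = ld_pair(&x[(size_t)(ii[p] - 1) * l], l,
                     &x[(size_t)(jj[p] - 1) * l], l);
  return out;
}

// Per-barcode pairwise penalty components over all unordered cross pairs
// of the set: component i is the sum of pair penalties over the N-1
// partners of barcode i, so each unordered pair contributes to both
// members.  hd_pen and cp_pen are value-indexed lookup vectors of length
// l+1 (index = factor value).  Self-pairs (self-dimers) are excluded.
// [[Rcpp::export]]
List pair_components_c(IntegerMatrix m, NumericVector hd_pen,
                       NumericVector cp_pen, int min_overlap, bool do_hd,
                       bool do_cp) {
  int n = m.nrow(), l = m.ncol();
  if (do_hd && hd_pen.size() < l + 1) stop("hd_pen too short");
  if (do_cp && cp_pen.size() < l + 1) stop("cp_pen too short");
  std::vector<int> x = flatten(m);
  NumericVector p_hd(n), p_cp(n);
  for (int i = 0; i < n; ++i) {
    const int *a = &x[(size_t)i * l];
    for (int j = i + 1; j < n; ++j) {
      const int *b = &x[(size_t)j * l];
      if (do_hd) {
        double s = hd_pen[hd_pair(a, b, l)];
        p_hd[i] += s;
        p_hd[j] += s;
      }
      if (do_cp) {
        double s = cp_pen[cp_pair(a, l, b, l, min_overlap)];
        p_cp[i] += s;
        p_cp[j] += s;
      }
    }
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["p_hd"] = p_hd, _["p_cp"] = p_cp);
}
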