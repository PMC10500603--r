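#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Column-wise mid-ranks with tie bookkeeping.
//
// For a genes-in-rows matrix (one column per brain region) returns, per
// column: mid-ranks of the non-missing entries (NA stays NA), the number of
// non-missing entries, and the tie-correction term sum(t^3 - t) over tied
// groups, as used in the tie-corrected variance of the Mann-Whitney normal
// approximation.
// [[Rcpp::export(name = ".col_ranks_cpp")]]
List col_ranks(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix ranks(nr, nc);
  NumericVector tie_term(nc), n_obs(nc);
  std::vector<std::pair<double, int> > v;
  v.reserve(nr);

  for (int j = 0; j < nc; ++j) {
    const double *col = &x(0, j);
    v.clear();
    for (int i = 0; i < nr; ++i) {
      if (NumericVector::is_na(col[i])) {
        ranks(i, j) = NA_REAL;
      } else {
        v.push_back(std::make_pair(col[i], i));
      }
    }
    const int n = (int) v.size();
    n_obs[j] = n;
    std::sort(v.begin(), v.end());
    double ties = 0.0;
    int i = 0;
    while (i < n) {
      int k = i + 1;
      while (k < n && v[k].first == v[i].first) ++k;
      const double t = k - i;
      const double mid = (i + 1 + k) / 2.0;  // average of ranks i+1 .. k
      for (int m = i; m < k; ++m) ranks(v[m].second, j) = mid;
      if (t > 1) ties += t * t * t - t;
      i = k;
    }
    tie_term[j] = ties;
  }
  return List::create(_["ranks"] = ranks,
                      _["n_obs"] = n_obs,
                      _["tie_term"] = tie_term);
}

// Open-addressing hash counter over double bit patterns (linear probing),
// used to find tied values within a column without sorting it.
struct TieCounter {
  std::vector<uint64_t> keys;
  std::vector<int> counts;
  std::vector<int> used;
  uint64_t mask;

  explicit TieCounter(size_t capacity) {
    size_t size = 1;
    while (size < capacity * 4) size <<= 1;  // load factor <= 0.25
    keys.assign(size, 0);
    counts.assign(size, 0);
    used.reserve(capacity);
    mask = size - 1;
  }
  static uint64_t hash(uint64_t h) {
    h ^= h >> 33; h *= 0xff51afd7ed558ccdULL;
    h ^= h >> 33; h *= 0xc4ceb9fe1a85ec53ULL;
    h ^= h >> 33;
    return h;
  }
  void add(double value) {
    if (value == 0.0) value = 0.0;  // collapse -0.0 onto +0.0
    uint64_t bits;
    std::memcpy(&bits, &value, sizeof bits);
    uint64_t slot = hash(bits) & mask;
    for (;;) {
      if (counts[slot] == 0) {
        keys[slot] = bits;
        counts[slot] = 1;
        used.push_back((int) slot);
        return;
      }
      if (keys[slot] == bits) {
        ++counts[slot];
        return;
      }
      slot = (slot + 1) & mask;
    }
  }
  double tie_term_and_reset() {
    double ties = 0.0;
    for (size_t u = 0; u < used.size(); ++u) {
      const double c = counts[used[u]];
      if (c > 1) ties += c * c * c - c;
      counts[used[u]] = 0;
    }
    used.clear();
    return ties;
  }
};

// Per-column Wilcoxon rank-sum bookkeeping for one or more gene sets,
// without materialising full rank matrices: for each region column of a
// genes-in-rows matrix and each target set, the rank sum W of the target
// genes (mid-ranks), the target-group size and value sum; plus, per
// column, the number of non-missing values, the tie-correction term over
// all values, and the sum of all values (for directions of mean
// differences).  Target indices are 1-based.  One pass over the matrix
// serves every set, so evaluating a list and its split halves costs a
// single sweep.
// An optional override block substitutes the values of selected rows
// (e.g. the target genes of a matched null atlas, whose background rows
// are bit-identical to the signal atlas): statistics are computed as if
// x had those rows replaced, without materialising the patched matrix.
// [[Rcpp::export(name = ".col_enrich_cpp")]]
List col_enrich(NumericMatrix x, List target_sets,
                Nullable<List> override = R_NilValue) {
  const int nr = x.nrow(), nc = x.ncol();
  const int K = target_sets.size();

  std::vector<int> ov_map(nr, -1);
  NumericMatrix ov_values;
  bool has_ov = false;
  if (override.isNotNull()) {
    List ov(override);
    IntegerVector ov_rows = ov["rows"];
    ov_values = as<NumericMatrix>(ov["values"]);
    if (ov_values.nrow() != ov_rows.size() || ov_values.ncol() != nc)
      stop("override values must be length(rows) x ncol(x)");
    for (int t = 0; t < ov_rows.size(); ++t) {
      if (ov_rows[t] < 1 || ov_rows[t] > nr)
        stop("override row index out of range");
      ov_map[ov_rows[t] - 1] = t;
    }
    has_ov = true;
  }
  NumericMatrix W(nc, K), n1_out(nc, K), s_target(nc, K);
  NumericVector n_obs(nc), tie_term(nc), s_all(nc);

  std::vector<std::vector<int> > tidx(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector rows = target_sets[k];
    tidx[k].resize(rows.size());
    for (int t = 0; t < rows.size(); ++t) {
      if (rows[t] < 1 || rows[t] > nr) stop("target row index out of range");
      tidx[k][t] = rows[t] - 1;
    }
  }
  // per-set scratch: sorted distinct target values with multiplicities,
  // strictly-below counts and tie counts
  std::vector<std::vector<double> > tv(K), less(K), eq(K), mult(K);
  TieCounter counter((size_t) nr);

  for (int j = 0; j < nc; ++j) {
    const double *col = &x(0, j);
    for (int k = 0; k < K; ++k) {
      tv[k].clear(); mult[k].clear();
      double st = 0.0;
      for (size_t t = 0; t < tidx[k].size(); ++t) {
        const int row = tidx[k][t];
        const double value = (has_ov && ov_map[row] >= 0)
          ? ov_values(ov_map[row], j) : col[row];
        if (!NumericVector::is_na(value)) {
          tv[k].push_back(value);
          st += value;
        }
      }
      n1_out(j, k) = (double) tv[k].size();
      s_target(j, k) = st;
      std::sort(tv[k].begin(), tv[k].end());
      int w = 0;
      for (size_t q = 0; q < tv[k].size(); ) {
        size_t q2 = q + 1;
        while (q2 < tv[k].size() && tv[k][q2] == tv[k][q]) ++q2;
        tv[k][w] = tv[k][q];
        mult[k].push_back((double) (q2 - q));
        ++w; q = q2;
      }
      tv[k].resize(w);
      less[k].assign(w + 1, 0.0);
      eq[k].assign(w, 0.0);
    }

    int N = 0;
    double sa = 0.0;
    for (int i = 0; i < nr; ++i) {
      const double value = (has_ov && ov_map[i] >= 0)
        ? ov_values(ov_map[i], j) : col[i];
      if (NumericVector::is_na(value)) continue;
      ++N;
      sa += value;
      counter.add(value);
      for (int k = 0; k < K; ++k) {
        const int w = (int) tv[k].size();
        if (w == 0) continue;
        const int pos = (int) (std::lower_bound(tv[k].begin(), tv[k].end(),
                                                value) - tv[k].begin());
        if (pos < w && tv[k][pos] == value) {
          eq[k][pos] += 1.0;
          less[k][pos + 1] += 1.0;  // < each strictly larger target value
        } else {
          less[k][pos] += 1.0;      // < tv[pos] and everything above it
        }
      }
    }
    for (int k = 0; k < K; ++k) {
      const int w = (int) tv[k].size();
      for (int q = 1; q <= w; ++q) less[k][q] += less[k][q - 1];
      double Wsum = 0.0;
      for (int q = 0; q < w; ++q) {
        Wsum += mult[k][q] * (less[k][q] + (eq[k][q] + 1.0) / 2.0);
      }
      W(j, k) = Wsum;
    }
    n_obs[j] = N;
    tie_term[j] = counter.tie_term_and_reset();
    s_all[j] = sa;
  }
  return List::create(_["W"] = W, _["n1"] = n1_out, _["n_obs"] = n_obs,
                      _["tie_term"] = tie_term, _["s_target"] = s_target,
                      _["s_all"] = s_all);
}

// Row-wise z-scoring (population SD) in two cache-friendly passes over a
// column-major matrix.  Rows with fewer than two observed values or zero
// variance become all-zero at observed cells (degenerate flag set); NA
// cells stay NA.
// [[Rcpp::export(name = ".row_zscore_cpp")]]
List row_zscore(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  std::vector<double> sum(nr, 0.0), sumsq(nr, 0.0);
  std::vector<int> cnt(nr, 0);
  for (int j = 0; j < nc; ++j) {
    const double *col = &x(0, j);
    for (int i = 0; i < nr; ++i) {
      const double value = col[i];
      if (NumericVector::is_na(value)) continue;
      sum[i] += value;
      sumsq[i] += value * value;
      ++cnt[i];
    }
  }
  std::vector<double> mu(nr, 0.0), inv_s(nr, 0.0);
  LogicalVector degenerate(nr);
  for (int i = 0; i < nr; ++i) {
    if (cnt[i] == 0) { degenerate[i] = FALSE; continue; }
    mu[i] = sum[i] / cnt[i];
    double v = sumsq[i] / cnt[i] - mu[i] * mu[i];
    if (v < 0) v = 0;
    const double s = std::sqrt(v);
    if (cnt[i] < 2 || s == 0.0) {
      degenerate[i] = TRUE;
      inv_s[i] = 0.0;  // z collapses to 0 at observed cells
      mu[i] = 0.0;
    } else {
      degenerate[i] = FALSE;
      inv_s[i] = 1.0 / s;
    }
  }
  NumericMatrix z(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double *col = &x(0, j);
    double *zcol = &z(0, j);
    for (int i = 0; i < nr; ++i) {
      const double value = col[i];
      zcol[i] = NumericVector::is_na(value)
        ? NA_REAL : (value - mu[i]) * inv_s[i];
    }
  }
  z.attr("dimnames") = x.attr("dimnames");
  return List::create(_["z"] = z, _["degenerate"] = degenerate);
}
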