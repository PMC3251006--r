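#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <cstring>
#include <numeric>
#include <utility>
#include <vector>
using namespace Rcpp;

// Ascending average ranks of v (ties share the mean of their positions).
// `pairs` is scratch space of length n.
static void avg_ranks(const std::vector<double>& v,
                      std::vector<std::pair<double, int> >& pairs,
                      std::vector<double>& out) {
  const int n = static_cast<int>(v.size());
  for (int i = 0; i < n; ++i) pairs[i] = std::make_pair(v[i], i);
  std::sort(pairs.begin(), pairs.end());
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && pairs[j + 1].first == pairs[i].first) ++j;
    const double r = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) out[pairs[k].second] = r;
    i = j + 1;
  }
}

// Column-wise ascending average ranks of a matrix.
// [[Rcpp::export]]
NumericMatrix cpp_col_avg_ranks(NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  std::vector<double> col(n), rk(n);
  std::vector<std::pair<double, int> > pairs(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) col[i] = x(i, j);
    avg_ranks(col, pairs, rk);
    for (int i = 0; i < n; ++i) out(i, j) = rk[i];
  }
  return out;
}

// Order-preserving map from IEEE double to uint64 (total order, equal
// doubles map to equal keys; +0.0 is canonicalised by the caller).
static inline uint64_t order_key(double d) {
  uint64_t u;
  std::memcpy(&u, &d, 8);
  return (u & 0x8000000000000000ULL) ? ~u : (u | 0x8000000000000000ULL);
}

// Mean log fold-change ranks over all case-control pairs.
//
// values: genes x samples (log scale); case_idx / ctrl_idx: 1-based column
// indices. For each pair (c, t) the per-gene difference values[,c] - values[,t]
// is ranked ascending with average ties (rank 1 = strongest decrease); the
// up-regulation rank is G + 1 - rank, an identity that holds exactly for
// average ranks. Returns per-gene means of log(rank) for both directions, from
// which geometric-mean ranks are exp(mean_log). Sorting uses an
// order-preserving integer key; untied ranks (the generic case for continuous
// data) take precomputed logs, tied average ranks fall back to std::log.
// [[Rcpp::export]]
List cpp_mean_log_ranks(NumericMatrix values, IntegerVector case_idx,
                        IntegerVector ctrl_idx) {
  const int G = values.nrow();
  const int nc = case_idx.size(), nt = ctrl_idx.size();
  const double H = static_cast<double>(nc) * nt;
  std::vector<double> logtab(G + 1);
  logtab[0] = 0.0;
  for (int i = 1; i <= G; ++i) logtab[i] = std::log(static_cast<double>(i));
  std::vector<std::pair<uint64_t, int> > pairs(G);
  NumericVector sum_up(G, 0.0), sum_down(G, 0.0);
  double* su = REAL(sum_up);
  double* sd = REAL(sum_down);
  const double* vp = REAL(values);
  for (int a = 0; a < nc; ++a) {
    const double* ca = vp + static_cast<size_t>(case_idx[a] - 1) * G;
    for (int b = 0; b < nt; ++b) {
      const double* tb = vp + static_cast<size_t>(ctrl_idx[b] - 1) * G;
      for (int g = 0; g < G; ++g) {
        pairs[g] = std::make_pair(order_key(ca[g] - tb[g] + 0.0), g);
      }
      std::sort(pairs.begin(), pairs.end());
      int i = 0;
      while (i < G) {
        int j = i;
        while (j + 1 < G && pairs[j + 1].first == pairs[i].first) ++j;
        if (j == i) {
          const int g = pairs[i].second;
          sd[g] += logtab[i + 1];
          su[g] += logtab[G - i];
        } else {
          const double rk = 0.5 * (i + j) + 1.0;
          const double ld = std::log(rk), lu = std::log(G + 1.0 - rk);
          for (int k = i; k <= j; ++k) {
            sd[pairs[k].second] += ld;
            su[pairs[k].second] += lu;
          }
        }
        i = j + 1;
      }
    }
  }
  for (int g = 0; g < G; ++g) {
    su[g] /= H;
    sd[g] /= H;
  }
  return List::create(_["mean_log_up"] = sum_up,
                      _["mean_log_down"] = sum_down);
}
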