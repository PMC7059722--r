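#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact run-length histogram of placement-start coverage.
//
// A placement start a on [1, a_max] is "covered" by contact interval
// [lo[i], hi[i]] (clamped); starts inside any exclusion zone
// [excl_lo[j], excl_hi[j]] are ineligible. Returns, for every coverage value
// observed over the eligible starts, the number of eligible start positions
// carrying that value: value[k], length[k]. Sampling placement counts i.i.d.
// from this histogram is distributionally identical to rejection-sampling
// uniform placements and counting captured contacts per placement.
//
// Events are radix-sorted by position (two 10-bit passes), then swept.
// [[Rcpp::export(name = ".cover_hist_cpp")]]
List cover_hist_cpp(NumericVector lo, NumericVector hi,
                    NumericVector excl_lo, NumericVector excl_hi,
                    double a_max) {
  const int M = static_cast<int>(a_max);
  const int m = lo.size(), e = excl_lo.size();
  // event encoding: position (1..M+1), type: 0 cover+1, 1 cover-1,
  // 2 excl+1, 3 excl-1
  std::vector<int> pos; std::vector<signed char> typ;
  pos.reserve(2 * (m + e) + 2); typ.reserve(2 * (m + e) + 2);
  for (int i = 0; i < m; ++i) {
    double l = lo[i], h = hi[i];
    if (l > h || h < 1 || l > M) continue;
    int li = l < 1 ? 1 : (int)l;
    int hi_ = h > M ? M : (int)h;
    pos.push_back(li); typ.push_back(0);
    pos.push_back(hi_ + 1); typ.push_back(1);
  }
  for (int j = 0; j < e; ++j) {
    double l = excl_lo[j], h = excl_hi[j];
    if (l > h || h < 1 || l > M) continue;
    int li = l < 1 ? 1 : (int)l;
    int hi_ = h > M ? M : (int)h;
    pos.push_back(li); typ.push_back(2);
    pos.push_back(hi_ + 1); typ.push_back(3);
  }
  const int ne = pos.size();
  // two-pass LSD radix sort on position (10 bits per pass, up to 2^20)
  std::vector<int> idx(ne), tmp(ne);
  for (int i = 0; i < ne; ++i) idx[i] = i;
  for (int shift = 0; shift <= 10; shift += 10) {
    int cnt[1025] = {0};
    for (int i = 0; i < ne; ++i) ++cnt[((pos[idx[i]] >> shift) & 1023) + 1];
    for (int b = 1; b <= 1024; ++b) cnt[b] += cnt[b - 1];
    for (int i = 0; i < ne; ++i) tmp[cnt[(pos[idx[i]] >> shift) & 1023]++] = idx[i];
    idx.swap(tmp);
  }
  // sweep
  std::vector<double> tally;   // tally[v] = eligible length with coverage v
  int cover = 0, excl = 0;
  int cur = 1;
  int i = 0;
  while (i < ne) {
    int p = pos[idx[i]];
    if (p > cur && excl == 0 && cur <= M) {
      int seg_end = p > M + 1 ? M + 1 : p;
      if (seg_end > cur) {
        if ((int)tally.size() <= cover) tally.resize(cover + 1, 0.0);
        tally[cover] += seg_end - cur;
      }
    }
    if (p > cur) cur = p;
    for (; i < ne && pos[idx[i]] == p; ++i) {
      switch (typ[idx[i]]) {
        case 0: ++cover; break;
        case 1: --cover; break;
        case 2: ++excl; break;
        case 3: --excl; break;
      }
    }
  }
  if (cur <= M && excl == 0) {
    if ((int)tally.size() <= cover) tally.resize(cover + 1, 0.0);
    tally[cover] += M - cur + 1;
  }
  std::vector<int> vals; std::vector<double> lens;
  for (int v = 0; v < (int)tally.size(); ++v)
    if (tally[v] > 0) { vals.push_back(v); lens.push_back(tally[v]); }
  return List::create(Named("value") = wrap(vals),
                      Named("length") = wrap(lens));
}

// Binary search into an already-sorted vector without the per-call sortedness
// re-check of findInterval(). Returns, for each query, the number of elements
// <= q (right = true) or < q (right = false).
// [[Rcpp::export(name = ".bisect_cpp")]]
IntegerVector bisect_cpp(NumericVector sorted, NumericVector q, bool right) {
  const int n = sorted.size(), m = q.size();
  const double *s = REAL(sorted);
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) {
    out[i] = right ? (std::upper_bound(s, s + n, q[i]) - s)
                   : (std::lower_bound(s, s + n, q[i]) - s);
  }
  return out;
}

// Inter-chromosomal placement counting: contacts sorted by pA with parallel
// pB; for each placement (a[i], b[i]) count contacts with
// pA in [a, a+L1-1] and pB in [b, b+L2-1].
// [[Rcpp::export(name = ".count_pairs_cpp")]]
IntegerVector count_pairs_cpp(NumericVector pA_sorted, NumericVector pB,
                              NumericVector a, NumericVector b,
                              double L1, double L2) {
  const int nc = pA_sorted.size(), n = a.size();
  const double *pa = REAL(pA_sorted);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int lo = std::lower_bound(pa, pa + nc, a[i]) - pa;
    int hi = std::upper_bound(pa, pa + nc, a[i] + L1 - 1) - pa;
    int cnt = 0;
    const double b1 = b[i], b2 = b[i] + L2 - 1;
    for (int k = lo; k < hi; ++k)
      if (pB[k] >= b1 && pB[k] <= b2) ++cnt;
    out[i] = cnt;
  }
  return out;
}
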