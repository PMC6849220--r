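#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <vector>
using namespace Rcpp;

// Suffix array by cyclic-shift doubling with counting sort, over an integer
// alphabet. A unique smallest terminator is appended internally so cyclic
// order equals suffix order; the terminator suffix is dropped from the result.
static std::vector<int> suffix_array(const std::vector<int>& text) {
  std::vector<long long> s(text.begin(), text.end());
  s.push_back(LLONG_MIN); // unique terminator, strictly smallest
  const int n = (int)s.size();
  // compress values to 0..m-1
  {
    std::vector<long long> vals(s);
    std::sort(vals.begin(), vals.end());
    vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
    for (int i = 0; i < n; ++i)
      s[i] = std::lower_bound(vals.begin(), vals.end(), s[i]) - vals.begin();
  }
  int classes = 0;
  std::vector<int> p(n), c(n), pn(n), cn(n);
  {
    for (int i = 0; i < n; ++i) c[i] = (int)s[i];
    classes = *std::max_element(c.begin(), c.end()) + 1;
    std::vector<int> cnt(std::max(classes, n), 0);
    for (int i = 0; i < n; ++i) cnt[c[i]]++;
    for (int i = 1; i < classes; ++i) cnt[i] += cnt[i - 1];
    for (int i = n - 1; i >= 0; --i) p[--cnt[c[i]]] = i;
  }
  std::vector<int> cnt(n, 0);
  for (int k = 1; k < n && classes < n; k <<= 1) {
    for (int i = 0; i < n; ++i) {
      pn[i] = p[i] - k;
      if (pn[i] < 0) pn[i] += n;
    }
    std::fill(cnt.begin(), cnt.begin() + classes, 0);
    for (int i = 0; i < n; ++i) cnt[c[pn[i]]]++;
    for (int i = 1; i < classes; ++i) cnt[i] += cnt[i - 1];
    for (int i = n - 1; i >= 0; --i) p[--cnt[c[pn[i]]]] = pn[i];
    cn[p[0]] = 0;
    classes = 1;
    for (int i = 1; i < n; ++i) {
      int a1 = c[p[i]], a2 = c[(p[i] + k) % n];
      int b1 = c[p[i - 1]], b2 = c[(p[i - 1] + k) % n];
      if (a1 != b1 || a2 != b2) ++classes;
      cn[p[i]] = classes - 1;
    }
    c.swap(cn);
  }
  // p[0] is the terminator position n-1; drop it
  return std::vector<int>(p.begin() + 1, p.end());
}

// Kasai LCP: lcp[k] = longest common prefix of suffixes sa[k-1] and sa[k].
static std::vector<int> lcp_array(const std::vector<int>& s,
                                  const std::vector<int>& sa) {
  const int n = (int)sa.size();
  std::vector<int> rank_(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

// Maximal unique matches over a combined integer text laid out as
//   [0, t_len)  target records (unique negative sentinels between records)
//   [t_len, n)  candidate forward then candidate reverse-complement
// Bases are coded 1..4; every N and every sentinel carries its own unique
// negative code, so no match can include an N or cross a record boundary.
//
// both_unique = true : matched string occurs exactly once in the target block
//   and exactly once in the candidate block (forward + reverse complement) —
//   equivalent to a suffix-array block of exactly two suffixes, one per side.
// both_unique = false: unique in the target only; candidate occurrences are
//   enumerated by scanning outward while the running-min LCP still exceeds the
//   longest prefix the target suffix shares with any other target suffix.
// [[Rcpp::export(name = ".mum_core")]]
DataFrame mum_core(IntegerVector text, int t_len, int min_len,
                   bool both_unique) {
  std::vector<int> s(text.begin(), text.end());
  const int n = (int)s.size();
  std::vector<int> out_t, out_c, out_l;
  if (n == 0 || t_len == 0 || t_len >= n)
    return DataFrame::create(_["tpos"] = out_t, _["cpos"] = out_c,
                             _["len"] = out_l);
  std::vector<int> sa = suffix_array(s);
  std::vector<int> lcp = lcp_array(s, sa);
  auto isT = [&](int p) { return p < t_len; };

  if (both_unique) {
    for (int k = 1; k < n; ++k) {
      int l = lcp[k];
      if (l < min_len) continue;
      int a = sa[k - 1], b = sa[k];
      if (isT(a) == isT(b)) continue;
      // the length-l prefix must be shared by exactly these two suffixes
      int prev = lcp[k - 1];            // lcp[0] == 0
      int next = (k + 1 < n) ? lcp[k + 1] : 0;
      if (prev >= l || next >= l) continue;
      // left-maximality (sentinels are unique, so equality implies a base)
      if (a > 0 && b > 0 && s[a - 1] == s[b - 1]) continue;
      int tp = isT(a) ? a : b;
      int cp = isT(a) ? b : a;
      out_t.push_back(tp);
      out_c.push_back(cp);
      out_l.push_back(l);
    }
  } else {
    const int INF = INT_MAX / 2;
    // running-min lcp to the nearest target suffix above / below each rank
    std::vector<int> upT(n, -1), downT(n, -1);
    {
      int cur = INF;
      bool seen = false;
      for (int k = 0; k < n; ++k) {
        if (k > 0) cur = std::min(cur, lcp[k]);
        upT[k] = seen ? cur : -1;
        if (isT(sa[k])) {
          seen = true;
          cur = INF;
        }
      }
      cur = INF;
      seen = false;
      for (int k = n - 1; k >= 0; --k) {
        if (k < n - 1) cur = std::min(cur, lcp[k + 1]);
        downT[k] = seen ? cur : -1;
        if (isT(sa[k])) {
          seen = true;
          cur = INF;
        }
      }
    }
    for (int k = 0; k < n; ++k) {
      if (!isT(sa[k])) continue;
      int i = sa[k];
      int u = std::max(upT[k], downT[k]);
      if (u < 0) u = 0;
      int bound = std::max(u, min_len - 1);
      int run = INF;
      for (int j = k - 1; j >= 0; --j) {
        run = std::min(run, lcp[j + 1]);
        if (run <= bound) break;
        int b = sa[j];
        if (isT(b)) break; // lcp to another target suffix is <= u anyway
        if (!(i > 0 && b > 0 && s[i - 1] == s[b - 1])) {
          out_t.push_back(i);
          out_c.push_back(b);
          out_l.push_back(run);
        }
      }
      run = INF;
      for (int j = k + 1; j < n; ++j) {
        run = std::min(run, lcp[j]);
        if (run <= bound) break;
        int b = sa[j];
        if (isT(b)) break;
        if (!(i > 0 && b > 0 && s[i - 1] == s[b - 1])) {
          out_t.push_back(i);
          out_c.push_back(b);
          out_l.push_back(run);
        }
      }
    }
  }
  return DataFrame::create(_["tpos"] = out_t, _["cpos"] = out_c,
                           _["len"] = out_l);
}

// Maximum-weight collinear chain (weighted LIS) over matches pre-sorted by
// (ref_start, qry_start). Compatibility: strictly non-overlapping and ordered
// on the reference axis; qry interval strictly after (plus strand) or strictly
// before (minus strand) the predecessor's. Ties on total weight resolve toward
// the chain whose first match comes earliest in the sorted order.
// Returns 1-based indices of the selected matches, in chain order.
// [[Rcpp::export(name = ".chain_core")]]
IntegerVector chain_core(IntegerVector rs, IntegerVector re, IntegerVector qs,
                         IntegerVector qe, NumericVector w,
                         bool minus_strand) {
  const int n = rs.size();
  if (n == 0) return IntegerVector(0);
  std::vector<double> dp(n);
  std::vector<int> par(n, -1), first(n);
  for (int j = 0; j < n; ++j) {
    dp[j] = w[j];
    first[j] = j;
    for (int i = 0; i < j; ++i) {
      if (re[i] > rs[j]) continue;
      if (!minus_strand) {
        if (qe[i] > qs[j]) continue;
      } else {
        if (qe[j] > qs[i]) continue;
      }
      double cand = dp[i] + w[j];
      if (cand > dp[j] || (cand == dp[j] && first[i] < first[j])) {
        dp[j] = cand;
        par[j] = i;
        first[j] = first[i];
      }
    }
  }
  int best = 0;
  for (int j = 1; j < n; ++j) {
    if (dp[j] > dp[best] || (dp[j] == dp[best] && first[j] < first[best]))
      best = j;
  }
  std::vector<int> sel;
  for (int j = best;; j = par[j]) {
    sel.push_back(j + 1);
    if (par[j] < 0) break;
  }
  std::reverse(sel.begin(), sel.end());
  return wrap(sel);
}
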