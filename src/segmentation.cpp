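// Bottom-up segmentation by t-test merging.
//
// Every probe starts as its own segment.  Welch two-sample t-tests compare
// each pair of adjacent segments; the pair with the largest P (most likely
// to share a mean) is merged, the merged segment's statistics are updated,
// and fresh tests against its neighbours are pushed.  Merging stops when
// the largest remaining P drops below the supplied critical value.
//
// Segments with fewer than 2 probes have no variance of their own; the
// caller supplies a global noise SD (scaled median absolute successive
// difference) used in their place, and such comparisons are z-tests.
// Exactly identical zero-variance segments compare with P = 1 (limiting
// behaviour), so constant stretches always merge first.  Ties on P are
// broken towards the leftmost pair, then insertion order, so reruns are
// deterministic.  The heap is lazily invalidated: entries referring to
// stale segment versions are discarded on pop.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static double welch_p(double n1, double m1, double v1,
                      double n2, double m2, double v2, double gvar) {
  bool use_z = (n1 < 2.0 || n2 < 2.0);
  double va = (n1 < 2.0) ? gvar : v1;
  double vb = (n2 < 2.0) ? gvar : v2;
  double se2 = va / n1 + vb / n2;
  if (se2 <= 0.0) return (m1 == m2) ? 1.0 : 0.0;
  double t = (m1 - m2) / std::sqrt(se2);
  if (use_z) return 2.0 * R::pnorm(-std::fabs(t), 0.0, 1.0, 1, 0);
  double a = (va / n1) * (va / n1) / (n1 - 1.0);
  double b = (vb / n2) * (vb / n2) / (n2 - 1.0);
  double df = (a + b <= 0.0) ? (n1 + n2 - 2.0) : se2 * se2 / (a + b);
  return 2.0 * R::pt(-std::fabs(t), df, 1, 0);
}

struct MergeEntry {
  double p;
  int left_first;   // first probe index of the left segment (tie-break)
  long long seq;    // insertion order (final tie-break)
  int li, ri;       // segment ids
  long long sl, sr; // segment version stamps at insertion
};

struct EntryCmp {
  bool operator()(const MergeEntry& a, const MergeEntry& b) const {
    if (a.p != b.p) return a.p < b.p;               // larger p first
    if (a.left_first != b.left_first) return a.left_first > b.left_first;
    return a.seq > b.seq;
  }
};

// [[Rcpp::export]]
List bottom_up_segment_cpp(NumericVector x, double alpha, double global_sd) {
  int n = x.size();
  if (n == 0) {
    return List::create(_["first"] = IntegerVector(0),
                        _["last"] = IntegerVector(0),
                        _["merge_p"] = NumericVector(0));
  }
  std::vector<double> sum(n), sumsq(n);
  std::vector<int> first(n), last(n), prev(n), nxt(n);
  std::vector<long long> stamp(n, 0);
  std::vector<bool> dead(n, false);
  std::vector<int> cnt(n);
  for (int i = 0; i < n; ++i) {
    sum[i] = x[i];
    sumsq[i] = x[i] * x[i];
    first[i] = i; last[i] = i; cnt[i] = 1;
    prev[i] = i - 1;
    nxt[i] = (i + 1 < n) ? i + 1 : -1;
  }
  double gvar = global_sd * global_sd;

  auto seg_mean = [&](int s) { return sum[s] / cnt[s]; };
  auto seg_var = [&](int s) {
    if (cnt[s] < 2) return 0.0;
    double v = (sumsq[s] - sum[s] * sum[s] / cnt[s]) / (cnt[s] - 1.0);
    return v > 0.0 ? v : 0.0;
  };

  std::priority_queue<MergeEntry, std::vector<MergeEntry>, EntryCmp> heap;
  long long seq = 0;
  auto push_pair = [&](int li, int ri) {
    if (li < 0 || ri < 0) return;
    double p = welch_p(cnt[li], seg_mean(li), seg_var(li),
                       cnt[ri], seg_mean(ri), seg_var(ri), gvar);
    heap.push(MergeEntry{p, first[li], seq++, li, ri, stamp[li], stamp[ri]});
  };
  for (int i = 0; i + 1 < n; ++i) push_pair(i, i + 1);

  std::vector<double> merge_p;
  while (!heap.empty()) {
    MergeEntry e = heap.top();
    if (e.p < alpha) break;
    heap.pop();
    if (dead[e.li] || dead[e.ri] ||
        stamp[e.li] != e.sl || stamp[e.ri] != e.sr) continue;
    // merge right segment into left
    merge_p.push_back(e.p);
    int li = e.li, ri = e.ri;
    sum[li] += sum[ri];
    sumsq[li] += sumsq[ri];
    cnt[li] += cnt[ri];
    last[li] = last[ri];
    nxt[li] = nxt[ri];
    if (nxt[ri] >= 0) prev[nxt[ri]] = li;
    dead[ri] = true;
    stamp[li]++; stamp[ri]++;
    push_pair(prev[li], li);
    push_pair(li, nxt[li]);
  }

  std::vector<int> f_out, l_out;
  int s = 0; // segment containing probe 0 is always id 0 (left absorbs right)
  while (s >= 0) {
    f_out.push_back(first[s] + 1);
    l_out.push_back(last[s] + 1);
    s = nxt[s];
  }
  return List::create(_["first"] = wrap(f_out),
                      _["last"] = wrap(l_out),
                      _["merge_p"] = wrap(merge_p));
}
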