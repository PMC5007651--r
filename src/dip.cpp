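#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Hartigan & Hartigan's dip statistic (the classical iterative algorithm).
//
// Work in count units on the sorted sample x_1..x_n. The empirical CDF is
// bracketed between its greatest convex minorant (GCM, fitted to the left
// limits, counts i-1) and least concave majorant (LCM, fitted to counts i).
// A candidate modal interval [low, high] is shrunk iteratively: within it
// the maximal gap d between the two hulls is located; the deviations of the
// CDF from the GCM over the flank discarded on the left (where a unimodal
// CDF must be convex) and from the LCM over the right flank (concave) are
// accumulated into the running dip; iteration stops when the interior gap
// no longer exceeds the accumulated value. The fitted unimodal CDF may jump
// at the mode, which is why hull touchpoints contribute the single-count
// atom offset (the "+1" terms). Final dip = accumulated / (2n).

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector xs) {
  const int n = xs.size();
  const std::vector<double> x(xs.begin(), xs.end());
  if (n < 2) stop("need at least 2 observations");
  if (x[0] == x[n - 1]) stop("degenerate sample: zero range");

  // global hull predecessor/successor chains (AS 217 style), 0-based:
  // mn[i] = previous touchpoint of the lower convex chain ending at i
  std::vector<int> mn(n), mj(n);
  mn[0] = 0;
  for (int i = 1; i < n; ++i) {
    mn[i] = i - 1;
    for (;;) {
      int j = mn[i];
      int k = mn[j];
      if (j == 0 ||
          (x[i] - x[j]) * (j - k) < (x[j] - x[k]) * (double)(i - j)) break;
      mn[i] = k;
    }
  }
  mj[n - 1] = n - 1;
  for (int i = n - 2; i >= 0; --i) {
    mj[i] = i + 1;
    for (;;) {
      int j = mj[i];
      int k = mj[j];
      if (j == n - 1 ||
          (x[i] - x[j]) * (j - k) < (x[j] - x[k]) * (double)(i - j)) break;
      mj[i] = k;
    }
  }

  int low = 0, high = n - 1;
  double dip = 1.0;  // the dip is never below one count (1/(2n) scaled)
  std::vector<int> g, l;  // g: high -> low (decreasing); l: low -> high

  for (int iter = 0; iter <= n; ++iter) {
    g.clear();
    g.push_back(high);
    while (g.back() > low) {
      int nxt = mn[g.back()];
      if (nxt < low) nxt = low;
      g.push_back(nxt);
    }
    l.clear();
    l.push_back(low);
    while (l.back() < high) {
      int nxt = mj[l.back()];
      if (nxt > high) nxt = high;
      l.push_back(nxt);
    }
    const int icx = (int)g.size(), icv = (int)l.size();

    double d = 0.0;
    int s_low = low, s_high = high;
    if (icx != 2 || icv != 2) {
      // walk both hull touchpoint lists in increasing x, measuring the gap
      // between each touchpoint of one hull and the opposite hull's segment
      int ix = icx - 2, iv = 1;
      do {
        int gi = g[ix], li = l[iv];
        if (gi > li) {
          // LCM touchpoint li lies inside GCM segment (g[ix+1], g[ix])
          int gp = g[ix + 1];
          double dx2 = x[gi] - x[gp];
          double interp = (dx2 > 0)
            ? gp + (x[li] - x[gp]) * (gi - gp) / dx2 : (double)gp;
          double dx = (li - interp) + 1.0;
          ++iv;
          if (dx >= d) { d = dx; s_low = gp; s_high = li; }
        } else {
          // GCM touchpoint gi lies inside LCM segment (l[iv-1], l[iv])
          int lp = l[iv - 1];
          double dx2 = x[li] - x[lp];
          double interp = (dx2 > 0)
            ? lp + (x[gi] - x[lp]) * (li - lp) / dx2 : (double)li;
          double dx = interp - gi + 1.0;
          --ix;
          if (dx > d) { d = dx; s_low = gi; s_high = li; }
        }
        if (ix < 0) ix = 0;
        if (iv > icv - 1) iv = icv - 1;
      } while (g[ix] != l[iv]);
    } else {
      d = 1.0;
    }
    if (d < dip) break;

    // flank deviations: CDF above the GCM over [low, s_low], and the LCM
    // above the CDF over [s_high, high]
    double dl = 0.0;
    for (size_t j = 0; j + 1 < g.size(); ++j) {
      if (g[j] > s_low) continue;  // only segments at or below the new low
      int hi_ = g[j], lo_ = g[j + 1];
      double dx2 = x[hi_] - x[lo_];
      for (int jr = lo_; jr <= hi_; ++jr) {
        double interp = (dx2 > 0)
          ? lo_ + (x[jr] - x[lo_]) * (hi_ - lo_) / dx2 : (double)lo_;
        double dxx = (jr - interp) + 1.0;
        if (dxx > dl) dl = dxx;
      }
    }
    double dr = 0.0;
    for (size_t j = 0; j + 1 < l.size(); ++j) {
      if (l[j] < s_high) continue;  // only segments at or above the new high
      int lo_ = l[j], hi_ = l[j + 1];
      double dx2 = x[hi_] - x[lo_];
      for (int jr = lo_; jr <= hi_; ++jr) {
        double interp = (dx2 > 0)
          ? lo_ + (x[jr] - x[lo_]) * (hi_ - lo_) / dx2 : (double)hi_;
        double dxx = interp - jr + 1.0;
        if (dxx > dr) dr = dxx;
      }
    }
    double dipnew = std::max(dl, dr);
    if (dipnew > dip) dip = dipnew;
    if (s_low == low && s_high == high) break;
    low = s_low;
    high = s_high;
  }
  return dip / (2.0 * n);
}
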