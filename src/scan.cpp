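#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// MATCH-style scoring of one integer-encoded sequence (1=A..4=T, 0=N) with an
// information-weighted frequency matrix w[i][b] = I(i) * f(i,b).
// MSS = (cur - min) / (max - min) over the whole matrix, CSS the same over the
// core positions. Offsets whose window overlaps an N score NA.
// [[Rcpp::export]]
List cpp_scan(IntegerVector s, NumericMatrix w, int core_start, int core_len) {
  const int L = w.nrow();
  const int n = s.size();
  const int noff = n - L + 1;
  if (noff < 1)
    return List::create(_["mss"] = NumericVector(0), _["css"] = NumericVector(0));

  std::vector<double> wmin(L), wmax(L);
  double minAll = 0, maxAll = 0, minCore = 0, maxCore = 0;
  for (int i = 0; i < L; ++i) {
    double lo = w(i, 0), hi = w(i, 0);
    for (int b = 1; b < 4; ++b) {
      lo = std::min(lo, w(i, b));
      hi = std::max(hi, w(i, b));
    }
    wmin[i] = lo; wmax[i] = hi;
    minAll += lo; maxAll += hi;
    if (i >= core_start - 1 && i < core_start - 1 + core_len) {
      minCore += lo; maxCore += hi;
    }
  }
  const double denAll = maxAll - minAll;
  const double denCore = maxCore - minCore;

  NumericVector mss(noff), css(noff);
  for (int o = 0; o < noff; ++o) {
    double cur = 0, curCore = 0;
    bool ok = true;
    for (int i = 0; i < L; ++i) {
      int b = s[o + i];
      if (b < 1 || b > 4) { ok = false; break; }
      double v = w(i, b - 1);
      cur += v;
      if (i >= core_start - 1 && i < core_start - 1 + core_len) curCore += v;
    }
    if (!ok) {
      mss[o] = NA_REAL; css[o] = NA_REAL;
    } else {
      mss[o] = denAll > 0 ? (cur - minAll) / denAll : 0.0;
      css[o] = denCore > 0 ? (curCore - minCore) / denCore : 0.0;
    }
  }
  return List::create(_["mss"] = mss, _["css"] = css);
}

// Best-window composite-module score per promoter.
//
// Hits are flattened across promoters and sorted by start within each
// promoter: hstart/hmss/hmot with ptr (0-based, length n_prom+1) giving the
// [ptr[p], ptr[p+1]) slice of promoter p. hmot is a 1-based motif-pool index
// and slot_of (length n_pool) maps pool index -> module slot 1..k (0 = motif
// not in the module).
//
// score(p) = max over candidate window starts s (every in-module hit start)
//   of sum_m wgt[m] * max(0, best mss of slot m with start in [s, s+W) -
//   theta[m]).
// Evaluated with one monotone-max deque per slot swept left to right, so the
// cost is linear in the promoter's module hits.
// [[Rcpp::export]]
NumericVector cpp_module_scores(IntegerVector hstart, NumericVector hmss,
                                IntegerVector hmot, IntegerVector ptr,
                                IntegerVector slot_of, NumericVector theta,
                                NumericVector wgt, int W) {
  const int k = theta.size();
  const int np = ptr.size() - 1;
  NumericVector out(np);
  std::vector<int> mst; mst.reserve(256);
  std::vector<double> mms; mms.reserve(256);
  std::vector<int> msl; msl.reserve(256);
  std::vector<std::deque<std::pair<int, double> > > dq(k);

  for (int p = 0; p < np; ++p) {
    mst.clear(); mms.clear(); msl.clear();
    for (int j = ptr[p]; j < ptr[p + 1]; ++j) {
      const int sl = slot_of[hmot[j] - 1];
      if (sl > 0) { mst.push_back(hstart[j]); mms.push_back(hmss[j]); msl.push_back(sl - 1); }
    }
    const int nm = (int) mst.size();
    double sc = 0.0;
    if (nm > 0) {
      for (int m = 0; m < k; ++m) dq[m].clear();
      int b = 0;
      for (int a = 0; a < nm; ++a) {
        const int s0 = mst[a];
        while (b < nm && mst[b] < s0 + W) {
          const int m = msl[b];
          while (!dq[m].empty() && dq[m].back().second <= mms[b]) dq[m].pop_back();
          dq[m].push_back(std::make_pair(mst[b], mms[b]));
          ++b;
        }
        double v = 0.0;
        for (int m = 0; m < k; ++m) {
          while (!dq[m].empty() && dq[m].front().first < s0) dq[m].pop_front();
          if (!dq[m].empty() && dq[m].front().second > theta[m])
            v += wgt[m] * (dq[m].front().second - theta[m]);
        }
        if (v > sc) sc = v;
      }
    }
    out[p] = sc;
  }
  return out;
}
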