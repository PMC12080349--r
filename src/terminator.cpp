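// Heuristic intrinsic (Rho-independent) terminator detector: a hairpin
// (stem of consecutive WC/GU pairs, optionally one internal mismatch for
// long stems, loop 3-10 nt) whose 3' side is followed within max_gap nt by
// a u_window-nt window containing at least u_min T residues.
// score = stem pairs + GC-pair count + best T-window count.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline bool tpair_ok(int a, int b) { // WC + GU (on DNA: G-T)
  return (a == 0 && b == 3) || (a == 3 && b == 0) ||
         (a == 1 && b == 2) || (a == 2 && b == 1) ||
         (a == 2 && b == 3) || (a == 3 && b == 2);
}
static inline bool tpair_gc(int a, int b) {
  return (a == 1 && b == 2) || (a == 2 && b == 1);
}

// [[Rcpp::export(name = ".terminator_scan_cpp")]]
DataFrame terminator_scan_cpp(IntegerVector xin, int stem_min, int loop_min,
                              int loop_max, int u_min, int u_window,
                              int max_gap, int max_mismatch,
                              int mismatch_min_stem) {
  std::vector<int> x(xin.begin(), xin.end());
  const int n = (int)x.size();
  std::vector<int> r_start, r_end, r_stem, r_loop, r_ucount;
  std::vector<double> r_score;

  // evaluate a stem candidate (outermost pair si..sj) against the U-tract
  // requirement; returns score or -1
  auto eval_tail = [&](int sj, int& bestT, int& bestWend) {
    bestT = -1; bestWend = -1;
    for (int g = 0; g <= max_gap; ++g) {
      const int w0 = sj + 1 + g;
      if (w0 + u_window > n) break;
      int t = 0;
      for (int p = w0; p < w0 + u_window; ++p) if (x[p] == 3) ++t;
      if (t > bestT) { bestT = t; bestWend = w0 + u_window - 1; }
    }
    return bestT >= u_min;
  };

  for (int l = 1; l + loop_min < n; ++l) { // l = 0-based loop start
    for (int L = loop_min; L <= loop_max; ++L) {
      if (l + L >= n) break;
      // extend outward from the innermost candidate pair (l-1, l+L);
      // the U-tract is tested at every extension point with enough pairs
      // (a maximal stem can overrun the poly-U tail via A.U pairs, so
      // non-maximal stems must be considered)
      double best_score = -1;
      int b_start = -1, b_end = -1, b_stem = 0, b_u = 0;
      int i = l - 1, j = l + L;
      int pairs = 0, gc = 0, mism = 0;
      while (i >= 0 && j < n) {
        if (tpair_ok(x[i], x[j])) {
          ++pairs; if (tpair_gc(x[i], x[j])) ++gc;
          const int need = (mism > 0) ? mismatch_min_stem : stem_min;
          if (pairs >= need) {
            int bt, bw;
            if (eval_tail(j, bt, bw)) {
              const double sc = (double)(pairs + gc + bt);
              if (sc > best_score) {
                best_score = sc; b_start = i; b_end = bw;
                b_stem = pairs; b_u = bt;
              }
            }
          }
        } else {
          if (mism >= max_mismatch || pairs == 0) break;
          ++mism; // bridge one interior mismatch
        }
        --i; ++j;
      }
      if (best_score < 0) continue;
      r_start.push_back(b_start + 1); // 1-based, stem 5' start
      r_end.push_back(b_end + 1);
      r_stem.push_back(b_stem);
      r_loop.push_back(L);
      r_ucount.push_back(b_u);
      r_score.push_back(best_score);
    }
  }
  return DataFrame::create(_["start"] = r_start, _["end"] = r_end,
                           _["stem_bp"] = r_stem, _["loop_len"] = r_loop,
                           _["u_count"] = r_ucount, _["score"] = r_score,
                           _["stringsAsFactors"] = false);
}
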