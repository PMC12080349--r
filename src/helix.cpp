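// Qualifying-helix search.
//
// A qualifying helix is a chain of Watson-Crick (optionally G.U) base pairs
// (i_1<...<i_B) x (j_1>...>j_B) within one sequence, read antiparallel,
// with >= k pairs, at most m interior unpaired (bulge / internal loop)
// nucleotides, and at least min_loop unpaired nucleotides between the two
// arms (checked at the innermost pair).  Mismatched opposing pairs are not
// scored as pairs; any skipped nucleotide counts toward m.
//
// Guide mode restricts the outermost pair's 3' position to the guide
// window (the last guide_len positions), i.e. the 3' arm must overlap it.
//
// DP over states (i, j, u) = innermost pair (i,j) with exactly u unpaired
// used; value = maximal pair count (tie: minimal 5' arm start).

#include <Rcpp.h>
#include "ecrmech.h"
using namespace Rcpp;

static inline bool pair_ok(int a, int b, bool allow_gu) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0) ||
      (a == 1 && b == 2) || (a == 2 && b == 1)) return true;
  if (allow_gu && ((a == 2 && b == 3) || (a == 3 && b == 2))) return true;
  return false;
}

// shared banded DP; early_exit stops at the first qualifying chain.
// Returns best qualifying pair count capped at k_cap (0 if none).
static int helix_dp(const std::vector<int>& x, int k_cap, int m, int min_loop,
                    int guide_start, bool allow_gu, bool early_exit) {
  const int n = (int)x.size();
  if (n < 2) return 0;
  int jband = 0;
  if (guide_start >= 0) {
    jband = guide_start - (k_cap - 1) - m;
    if (jband < 0) jband = 0;
  }
  const int W = n - jband;            // j ranges over [jband, n)
  if (W <= 0) return 0;
  std::vector<short> bp((size_t)(m + 1) * n * W, 0);
  auto at = [&](int u, int i, int j) -> short& {
    return bp[((size_t)u * n + i) * W + (j - jband)];
  };
  int best = 0;
  for (int i = 0; i < n; ++i) {
    const int xi = x[i];
    for (int j = n - 1; j > i && j >= jband; --j) {
      if (!pair_ok(xi, x[j], allow_gu)) continue;
      const bool loop_ok = (j - i - 1) >= min_loop;
      for (int u = 0; u <= m; ++u) {
        int v = 0;
        if (u == 0 && (guide_start < 0 || j >= guide_start)) v = 1;
        for (int a = 0; a <= u; ++a) {
          const int ip = i - 1 - a;
          if (ip < 0) break;
          for (int b = 0; b + a <= u; ++b) {
            const int jp = j + 1 + b;
            if (jp >= n) break;
            const short prev = at(u - a - b, ip, jp);
            if (prev > 0 && prev + 1 > v) v = prev + 1;
          }
        }
        if (v > k_cap) v = k_cap;
        at(u, i, j) = (short)v;
        if (loop_ok && v > best) {
          best = v;
          if (early_exit && best >= k_cap) return best;
        }
      }
    }
  }
  return best;
}

bool helix_exists_core(const std::vector<int>& x, int k, int m, int min_loop,
                       int guide_start, bool allow_gu) {
  return helix_dp(x, k, m, min_loop, guide_start, allow_gu, true) >= k;
}

int helix_maxbp_core(const std::vector<int>& x, int k_cap, int m, int min_loop,
                     int guide_start, bool allow_gu) {
  return helix_dp(x, k_cap, m, min_loop, guide_start, allow_gu, false);
}

// [[Rcpp::export(name = ".helix_exists_cpp")]]
bool helix_exists_cpp(IntegerVector x, int k, int m, int min_loop,
                      int guide_start, bool allow_gu) {
  std::vector<int> v(x.begin(), x.end());
  return helix_exists_core(v, k, m, min_loop, guide_start, allow_gu);
}

// [[Rcpp::export(name = ".helix_null_count_cpp")]]
int helix_null_count_cpp(IntegerVector x, int k, int m, int min_loop,
                         int guide_start, bool allow_gu, int n_shuffles) {
  std::vector<int> v(x.begin(), x.end());
  int cnt = 0;
  for (int s = 0; s < n_shuffles; ++s) {
    std::vector<int> sh = dinuc_shuffle_core(v);
    if (helix_exists_core(sh, k, m, min_loop, guide_start, allow_gu)) ++cnt;
  }
  return cnt;
}

// [[Rcpp::export(name = ".helix_maxbp_cpp")]]
int helix_maxbp_cpp(IntegerVector x, int k_cap, int m, int min_loop,
                    int guide_start, bool allow_gu) {
  std::vector<int> v(x.begin(), x.end());
  return helix_maxbp_core(v, k_cap, m, min_loop, guide_start, allow_gu);
}

// shuffle null for a parameter grid: best qualifying pair count (capped at
// k_cap) per shuffle and per max-unpaired value
// [[Rcpp::export(name = ".helix_shuffle_maxbp_cpp")]]
IntegerMatrix helix_shuffle_maxbp_cpp(IntegerVector x, int k_cap,
                                      IntegerVector m_values, int min_loop,
                                      int guide_start, bool allow_gu,
                                      int n_shuffles) {
  std::vector<int> v(x.begin(), x.end());
  IntegerMatrix out(n_shuffles, m_values.size());
  for (int s = 0; s < n_shuffles; ++s) {
    std::vector<int> sh = dinuc_shuffle_core(v);
    for (int q = 0; q < m_values.size(); ++q)
      out(s, q) = helix_maxbp_core(sh, k_cap, m_values[q], min_loop,
                                   guide_start, allow_gu);
  }
  return out;
}

// Full search with traceback: returns the chain maximizing
// (pair count, -unpaired, 5'-most arm_a start).
// [[Rcpp::export(name = ".helix_best_cpp")]]
List helix_best_cpp(IntegerVector xin, int k, int m, int min_loop,
                    int guide_start, bool allow_gu) {
  std::vector<int> x(xin.begin(), xin.end());
  const int n = (int)x.size();
  if (n < 2) return List::create(_["found"] = false);
  std::vector<short> bp((size_t)(m + 1) * n * n, 0);
  std::vector<short> a1((size_t)(m + 1) * n * n, 0);   // 5'-most arm_a start of best chain
  std::vector<short> par((size_t)(m + 1) * n * n, -1); // a*16+b predecessor code, -2 = start
  auto id = [&](int u, int i, int j) { return ((size_t)u * n + i) * n + j; };

  for (int i = 0; i < n; ++i) {
    const int xi = x[i];
    for (int j = n - 1; j > i; --j) {
      if (!pair_ok(xi, x[j], allow_gu)) continue;
      for (int u = 0; u <= m; ++u) {
        int v = 0; short vi1 = (short)i; short vpar = -1;
        if (u == 0 && (guide_start < 0 || j >= guide_start)) { v = 1; vpar = -2; }
        for (int a = 0; a <= u; ++a) {
          const int ip = i - 1 - a;
          if (ip < 0) break;
          for (int b = 0; b + a <= u; ++b) {
            const int jp = j + 1 + b;
            if (jp >= n) break;
            const size_t pid = id(u - a - b, ip, jp);
            const short prev = bp[pid];
            if (prev <= 0) continue;
            if (prev + 1 > v || (prev + 1 == v && a1[pid] < vi1)) {
              v = prev + 1; vi1 = a1[pid]; vpar = (short)(a * 16 + b);
            }
          }
        }
        bp[id(u, i, j)] = (short)v;
        a1[id(u, i, j)] = vi1;
        par[id(u, i, j)] = vpar;
      }
    }
  }

  // pick best qualifying state: (bp desc, u asc, i1 asc, then scan order)
  int Bbp = 0, Bu = 0, Bi = -1, Bj = -1; short Bi1 = 0;
  for (int u = 0; u <= m; ++u)
    for (int i = 0; i < n; ++i)
      for (int j = i + min_loop + 1; j < n; ++j) {
        const short v = bp[id(u, i, j)];
        if (v < k) continue;
        const short i1 = a1[id(u, i, j)];
        if (v > Bbp || (v == Bbp && (u < Bu || (u == Bu && i1 < Bi1)))) {
          Bbp = v; Bu = u; Bi = i; Bj = j; Bi1 = i1;
        }
      }
  if (Bi < 0) return List::create(_["found"] = false);

  // traceback (innermost -> outermost)
  std::vector<int> pi, pj;
  int i = Bi, j = Bj, u = Bu;
  while (true) {
    pi.push_back(i + 1); pj.push_back(j + 1);
    const short code = par[id(u, i, j)];
    if (code == -2) break;
    if (code < 0) stop("helix traceback failure");
    const int a = code / 16, b = code % 16;
    const int ni = i - 1 - a, nj = j + 1 + b, nu = u - a - b;
    i = ni; j = nj; u = nu;
  }
  const int B = (int)pi.size();
  IntegerMatrix pairs(B, 2);
  for (int t = 0; t < B; ++t) { // outermost first
    pairs(t, 0) = pi[B - 1 - t];
    pairs(t, 1) = pj[B - 1 - t];
  }
  return List::create(_["found"] = true, _["bp"] = Bbp, _["unpaired"] = Bu,
                      _["pairs"] = pairs);
}
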