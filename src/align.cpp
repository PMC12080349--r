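// Pairwise DNA alignment engines.
//
// Global: Needleman-Wunsch/Gotoh with affine gaps and separately priced
// terminal (end) gaps, as in EMBOSS needle with -endweight.  A gap of
// length L costs open + L*extend; terminal gaps cost end_open + L*end_extend.
//
// Local: Smith-Waterman with the same affine convention, single best path
// within a subject window (the R driver handles masking / multiple hits).
//
// Traceback tie-break: substitution > gap in a (gap char in the first
// sequence, consuming b) > gap in b.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const double NEG = -1e18;

// state codes: M = residue column, GA = gap column consuming a (gap char in
// b's row), GB = gap column consuming b (gap char in a's row)
enum { FROM_M = 0, FROM_GA = 1, FROM_GB = 2, FROM_START = 3 };

// [[Rcpp::export(name = ".global_align_cpp")]]
List global_align_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_ext,
                      double end_open, double end_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  std::vector<double> M((n + 1) * (m + 1), NEG), GA(M), GB(M);
  std::vector<unsigned char> tbM(M.size(), FROM_START), tbGA(M.size(), FROM_START),
      tbGB(M.size(), FROM_START);

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) { // prefix gap consuming a
    GA[idx(i, 0)] = -(end_open + i * end_ext);
    tbGA[idx(i, 0)] = (i == 1) ? FROM_START : FROM_GA;
  }
  for (int j = 1; j <= m; ++j) { // prefix gap consuming b
    GB[idx(0, j)] = -(end_open + j * end_ext);
    tbGB[idx(0, j)] = (j == 1) ? FROM_START : FROM_GB;
  }

  const double open1 = gap_open + gap_ext;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
      double vm = M[idx(i - 1, j - 1)], vga = GA[idx(i - 1, j - 1)],
             vgb = GB[idx(i - 1, j - 1)];
      double best = vm; unsigned char who = FROM_M;
      if (vgb > best) { best = vgb; who = FROM_GB; }
      if (vga > best) { best = vga; who = FROM_GA; }
      M[idx(i, j)] = best + s; tbM[idx(i, j)] = who;

      double o_m = M[idx(i - 1, j)] - open1;
      double o_ga = GA[idx(i - 1, j)] - gap_ext;
      double o_gb = GB[idx(i - 1, j)] - open1;
      best = o_m; who = FROM_M;
      if (o_gb > best) { best = o_gb; who = FROM_GB; }
      if (o_ga > best) { best = o_ga; who = FROM_GA; }
      GA[idx(i, j)] = best; tbGA[idx(i, j)] = who;

      o_m = M[idx(i, j - 1)] - open1;
      o_gb = GB[idx(i, j - 1)] - gap_ext;
      o_ga = GA[idx(i, j - 1)] - open1;
      best = o_m; who = FROM_M;
      if (o_gb > best) { best = o_gb; who = FROM_GB; }
      if (o_ga > best) { best = o_ga; who = FROM_GA; }
      GB[idx(i, j)] = best; tbGB[idx(i, j)] = who;
    }
  }

  // Final score: allow an end-priced suffix gap appended to the last row or
  // column.  The suffix gap extends from M or the opposite gap state so a
  // single gap run is never split between internal and terminal pricing.
  auto endgap = [&](int L) { return L == 0 ? 0.0 : -(end_open + L * end_ext); };
  double bestScore = NEG;
  int bi = n, bj = m, bstate = FROM_M, bsuffix = 0; // 1 = consuming a, 2 = consuming b
  {
    double cands[3] = { M[idx(n, m)], GA[idx(n, m)], GB[idx(n, m)] };
    int order[3] = { FROM_M, FROM_GB, FROM_GA };
    for (int t = 0; t < 3; ++t)
      if (cands[order[t]] > bestScore) { bestScore = cands[order[t]]; bstate = order[t]; }
  }
  for (int i = 0; i < n; ++i) { // suffix gap consuming a[i+1..n]
    double vm = (i == 0 && m == 0) ? NEG : M[idx(i, m)];
    double vgb = GB[idx(i, m)];
    double base = std::max(vm, vgb);
    double v = base + endgap(n - i);
    if (v > bestScore) {
      bestScore = v; bi = i; bj = m; bsuffix = 1;
      bstate = (vm >= vgb) ? FROM_M : FROM_GB;
    }
  }
  for (int j = 0; j < m; ++j) { // suffix gap consuming b[j+1..m]
    double vm = M[idx(n, j)];
    double vga = GA[idx(n, j)];
    double base = std::max(vm, vga);
    double v = base + endgap(m - j);
    if (v > bestScore) {
      bestScore = v; bi = n; bj = j; bsuffix = 2;
      bstate = (vm >= vga) ? FROM_M : FROM_GA;
    }
  }

  std::string out_a, out_b;
  if (bsuffix == 1) for (int i = n; i > bi; --i) { out_a += a[i - 1]; out_b += '-'; }
  if (bsuffix == 2) for (int j = m; j > bj; --j) { out_a += '-'; out_b += b[j - 1]; }
  int i = bi, j = bj, state = bstate;
  while (i > 0 || j > 0) {
    if (state == FROM_M) {
      unsigned char prev = tbM[idx(i, j)];
      out_a += a[i - 1]; out_b += b[j - 1];
      --i; --j; state = prev;
    } else if (state == FROM_GA) {
      unsigned char prev = tbGA[idx(i, j)];
      out_a += a[i - 1]; out_b += '-';
      --i; state = prev;
    } else if (state == FROM_GB) {
      unsigned char prev = tbGB[idx(i, j)];
      out_a += '-'; out_b += b[j - 1];
      --j; state = prev;
    } else {
      stop("traceback failure"); // unreachable on well-formed tables
    }
    if (state == FROM_START && (i > 0 || j > 0))
      stop("traceback failure");
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());

  return List::create(_["aligned_a"] = out_a, _["aligned_b"] = out_b,
                      _["score"] = bestScore);
}

// [[Rcpp::export(name = ".local_align_cpp")]]
List local_align_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  std::vector<double> M((n + 1) * (m + 1), 0.0), GA(M.size(), NEG), GB(M.size(), NEG);
  std::vector<unsigned char> tbM(M.size(), FROM_START), tbGA(M.size(), FROM_START),
      tbGB(M.size(), FROM_START);
  for (int i = 0; i <= n; ++i) M[idx(i, 0)] = 0.0;
  for (int j = 0; j <= m; ++j) M[idx(0, j)] = 0.0;

  const double open1 = gap_open + gap_ext;
  double bestScore = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
      double vm = M[idx(i - 1, j - 1)], vga = GA[idx(i - 1, j - 1)],
             vgb = GB[idx(i - 1, j - 1)];
      double best = vm; unsigned char who = FROM_M;
      if (vgb > best) { best = vgb; who = FROM_GB; }
      if (vga > best) { best = vga; who = FROM_GA; }
      double val = best + s;
      if (val < 0) val = 0;
      M[idx(i, j)] = val; tbM[idx(i, j)] = who;

      double o_m = M[idx(i - 1, j)] - open1;
      double o_ga = GA[idx(i - 1, j)] - gap_ext;
      double o_gb = GB[idx(i - 1, j)] - open1;
      best = o_m; who = FROM_M;
      if (o_gb > best) { best = o_gb; who = FROM_GB; }
      if (o_ga > best) { best = o_ga; who = FROM_GA; }
      GA[idx(i, j)] = best; tbGA[idx(i, j)] = who;

      o_m = M[idx(i, j - 1)] - open1;
      o_gb = GB[idx(i, j - 1)] - gap_ext;
      o_ga = GA[idx(i, j - 1)] - open1;
      best = o_m; who = FROM_M;
      if (o_gb > best) { best = o_gb; who = FROM_GB; }
      if (o_ga > best) { best = o_ga; who = FROM_GA; }
      GB[idx(i, j)] = best; tbGB[idx(i, j)] = who;

      if (M[idx(i, j)] > bestScore) { bestScore = M[idx(i, j)]; bi = i; bj = j; }
    }
  }
  if (bestScore <= 0) return List::create(_["score"] = 0.0);

  std::string out_a, out_b;
  int i = bi, j = bj, state = FROM_M;
  while (i > 0 && j > 0) {
    if (state == FROM_M) {
      if (M[idx(i, j)] <= 0) break;
      unsigned char prev = tbM[idx(i, j)];
      out_a += a[i - 1]; out_b += b[j - 1];
      --i; --j;
      if (prev == FROM_M && M[idx(i, j)] <= 0) break;
      state = prev;
    } else if (state == FROM_GA) {
      unsigned char prev = tbGA[idx(i, j)];
      out_a += a[i - 1]; out_b += '-';
      --i; state = prev;
    } else {
      unsigned char prev = tbGB[idx(i, j)];
      out_a += '-'; out_b += b[j - 1];
      --j; state = prev;
    }
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());
  return List::create(_["score"] = bestScore,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["aligned_a"] = out_a, _["aligned_b"] = out_b);
}
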