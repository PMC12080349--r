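// Intermolecular RNA-RNA hybridization energy under a nearest-neighbour
// model: Turner-style stack free energies (37C, kcal/mol) for
// Watson-Crick stacks, a simplified constant for wobble-containing stacks,
// a duplex initiation penalty, and a fixed per-nucleotide penalty for
// bulge/internal-loop nucleotides.  No intramolecular accessibility term.
//
// Strands hybridize antiparallel: pair (i on a, j on b), next pair inward
// is (i+1.., j-1..).  DP over "last pair" states; minimum free energy.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// pair codes (top strand base : bottom strand base): AU=0 UA=1 GC=2 CG=3 GU=4 UG=5
static inline int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// stack[p1][p2]: 5'-X Y-3' over 3'-W Z-5' with p1 = X:W, p2 = Y:Z
// (Turner 2004 Watson-Crick values; wobble-containing stacks simplified:
// one wobble pair -1.2, two wobble pairs -0.5)
static double stack_energy(int p1, int p2) {
  static const double wc[4][4] = {
    //            AU     UA     GC     CG      (p2)
    /* AU */ { -0.93, -1.10, -2.08, -2.24 },
    /* UA */ { -1.33, -0.93, -2.11, -2.35 },
    /* GC */ { -2.35, -2.24, -3.26, -3.42 },
    /* CG */ { -2.11, -2.08, -2.36, -3.26 }
  };
  const bool w1 = p1 >= 4, w2 = p2 >= 4;
  if (!w1 && !w2) return wc[p1][p2];
  if (w1 && w2) return -0.5;
  return -1.2;
}

// [[Rcpp::export(name = ".duplex_energy_cpp")]]
List duplex_energy_cpp(IntegerVector ain, IntegerVector bin,
                       double init, double loop_pen, int max_loop) {
  std::vector<int> a(ain.begin(), ain.end()), b(bin.begin(), bin.end());
  const int n = (int)a.size(), m = (int)b.size();
  const double INF = 1e18;
  // H[i][j] = best energy of a duplex whose last (3'-most on a) pair is (i,j)
  std::vector<double> H((size_t)n * m, INF);
  std::vector<int> par((size_t)n * m, -1); // packed i'*m+j', -1 = duplex start
  auto id = [m](int i, int j) { return (size_t)i * m + j; };

  double best = INF; int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      const int pc = pair_code(a[i], b[j]);
      if (pc < 0) continue;
      double v = init; int p = -1;
      // stack
      if (i > 0 && j + 1 < m) {
        const int ppc = pair_code(a[i - 1], b[j + 1]);
        if (ppc >= 0 && H[id(i - 1, j + 1)] < INF) {
          const double cand = H[id(i - 1, j + 1)] + stack_energy(ppc, pc);
          if (cand < v) { v = cand; p = (i - 1) * m + (j + 1); }
        }
      }
      // bulge / internal loop
      for (int la = 0; la <= max_loop; ++la) {
        const int ip = i - 1 - la;
        if (ip < 0) break;
        for (int lb = (la == 0 ? 1 : 0); la + lb <= max_loop; ++lb) {
          const int jp = j + 1 + lb;
          if (jp >= m) break;
          if (H[id(ip, jp)] >= INF) continue;
          const double cand = H[id(ip, jp)] + loop_pen * (la + lb);
          if (cand < v) { v = cand; p = ip * m + jp; }
        }
      }
      H[id(i, j)] = v; par[id(i, j)] = p;
      if (v < best) { best = v; bi = i; bj = j; }
    }
  }
  if (bi < 0 || best >= -1e-9) // at or above 0 within float tolerance
    return List::create(_["interaction"] = false);

  std::vector<int> pi, pj;
  int cur = bi * m + bj;
  while (cur >= 0) {
    pi.push_back(cur / m + 1); pj.push_back(cur % m + 1);
    cur = par[id(cur / m, cur % m)];
  }
  const int B = (int)pi.size();
  IntegerMatrix pairs(B, 2);
  for (int t = 0; t < B; ++t) { // 5'-most pair on a first
    pairs(t, 0) = pi[B - 1 - t];
    pairs(t, 1) = pj[B - 1 - t];
  }
  return List::create(_["interaction"] = true, _["energy"] = best,
                      _["n_pairs"] = B, _["pairs"] = pairs);
}
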