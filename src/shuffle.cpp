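// Exact dinucleotide-preserving shuffle (Altschul & Erickson 1985).
//
// The sequence is viewed as an Eulerian path in the multigraph whose edges
// are its consecutive dinucleotides.  A uniform random Eulerian path with
// the same start/end vertices is generated by (i) picking a random "last
// out-edge" per vertex until the chosen edges form an arborescence into the
// terminal vertex (rejection sampling), (ii) permuting the remaining
// out-edges uniformly, and (iii) walking the graph.  Endpoints and the full
// dinucleotide count multiset are preserved exactly.

#include <Rcpp.h>
#include "ecrmech.h"
using namespace Rcpp;

static inline int runif_int(int n) { // uniform on 0..n-1 using R's RNG
  int k = (int)std::floor(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

std::vector<int> dinuc_shuffle_core(const std::vector<int>& x) {
  const int n = (int)x.size();
  const int A = 5; // alphabet A,C,G,T,other
  if (n < 2) return x;

  std::vector<std::vector<int>> out(A); // out-edge target lists
  for (int t = 0; t + 1 < n; ++t) out[x[t]].push_back(x[t + 1]);
  const int s0 = x[0], sL = x[n - 1];

  // choose last out-edges forming an arborescence into sL
  std::vector<int> last(A, -1); // index into out[v] of chosen last edge
  for (int iter = 0; ; ++iter) {
    if (iter > 100000) stop("dinucleotide shuffle failed to converge");
    for (int v = 0; v < A; ++v)
      last[v] = (v != sL && !out[v].empty()) ? runif_int((int)out[v].size()) : -1;
    bool ok = true;
    for (int v = 0; v < A && ok; ++v) {
      if (v == sL || out[v].empty()) continue;
      int cur = v, steps = 0;
      while (cur != sL) {
        if (out[cur].empty() || last[cur] < 0) { ok = false; break; }
        cur = out[cur][last[cur]];
        if (++steps > A) { ok = false; break; } // cycle
      }
    }
    if (ok) break;
  }

  // permute non-last out-edges, then append the chosen last edge
  std::vector<std::vector<int>> ordered(A);
  for (int v = 0; v < A; ++v) {
    std::vector<int> rest;
    rest.reserve(out[v].size());
    for (int e = 0; e < (int)out[v].size(); ++e)
      if (e != last[v]) rest.push_back(out[v][e]);
    for (int e = (int)rest.size() - 1; e > 0; --e)
      std::swap(rest[e], rest[runif_int(e + 1)]);
    if (last[v] >= 0) rest.push_back(out[v][last[v]]);
    ordered[v] = rest;
  }

  std::vector<int> res(n);
  std::vector<int> ptr(A, 0);
  res[0] = s0;
  int cur = s0;
  for (int t = 1; t < n; ++t) {
    cur = ordered[cur][ptr[cur]++];
    res[t] = cur;
  }
  return res;
}

// [[Rcpp::export(name = ".dinuc_shuffle_cpp")]]
IntegerVector dinuc_shuffle_cpp(IntegerVector x) {
  std::vector<int> v(x.begin(), x.end());
  std::vector<int> r = dinuc_shuffle_core(v);
  return IntegerVector(r.begin(), r.end());
}
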