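#ifndef ECRMECH_H
#define ECRMECH_H

#include <vector>

// exact dinucleotide-preserving shuffle (Altschul-Erickson Eulerian walk);
// caller must hold an Rcpp RNGScope (automatic in exported functions)
std::vector<int> dinuc_shuffle_core(const std::vector<int>& x);

// qualifying-helix search cores; x holds base codes A=0,C=1,G=2,T=3,other=4.
// guide_start is 0-based index of the first guide-window position, or -1 for
// intra mode.  Returns best qualifying base-pair count (capped at k_cap,
// 0 if none); helix_exists_core returns early on the first qualifying chain.
bool helix_exists_core(const std::vector<int>& x, int k, int m, int min_loop,
                       int guide_start, bool allow_gu);
int helix_maxbp_core(const std::vector<int>& x, int k_cap, int m, int min_loop,
                     int guide_start, bool allow_gu);

#endif
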