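#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair weights: GC/CG -3, AU/TA -2, GU/TG -1 (T treated as U), else no pair.
static inline int pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -1;
  return 0;
}

// Minimum-energy Nussinov-style fold: maximize weighted base pairs with a
// minimum hairpin loop of 3 unpaired bases between the ends of any pair.
// Energies are <= 0; the empty structure has energy 0.
// [[Rcpp::export(name = ".nussinov_energy")]]
int nussinov_energy(std::string seq) {
  const int n = (int) seq.size();
  if (n < 5) return 0;
  std::vector<int> E((size_t) n * n, 0);
  // E[i + n*j] = min energy on closed interval [i, j]
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = E[(i + 1) + n * j];  // i unpaired
      for (int k = i + 4; k <= j; ++k) {
        int e = pair_energy(seq[(size_t) i], seq[(size_t) k]);
        if (e == 0) continue;
        int inner = (k - 1 >= i + 1) ? E[(i + 1) + n * (k - 1)] : 0;
        int right = (k + 1 <= j) ? E[(k + 1) + n * j] : 0;
        int cand = e + inner + right;
        if (cand < best) best = cand;
      }
      E[i + n * j] = best;
    }
  }
  return E[0 + n * (n - 1)];
}
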