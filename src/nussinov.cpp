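#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair-additive secondary-structure DP (Nussinov-style energy minimization).
// Energies: GC/CG -3, AU/UA -2, GU/UG -1; hairpin loops need >= 3 unpaired
// nucleotides; no pseudoknots. Traceback prefers the unpaired branch, then
// the smallest-index pairing partner, giving one deterministic structure.

static inline int pair_energy(char a, char b, bool wobble) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2;
  if (wobble && ((a == 'G' && b == 'U') || (a == 'U' && b == 'G'))) return -1;
  return 1; // sentinel: not pairable
}

// [[Rcpp::export]]
List nussinov_fold(std::string seq, int min_loop = 3, bool wobble = true) {
  int n = seq.size();
  if (n == 0) return List::create(_["mfe"] = 0.0, _["structure"] = "");
  // E[i][j]: min energy of subsequence [i, j], 0-based inclusive
  std::vector<std::vector<int> > E(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = E[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int e = pair_energy(seq[i], seq[k], wobble);
        if (e > 0) continue;
        int inner = (k - i > min_loop + 1) ? E[i + 1][k - 1] : 0;
        int outer = (k < j) ? E[k + 1][j] : 0;
        int cand = e + inner + outer;
        if (cand < best) best = cand;
      }
      E[i][j] = best;
    }
  }
  // traceback
  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i <= min_loop) continue;
    if (E[i][j] == E[i + 1][j]) { // prefer unpaired
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) { // smallest partner first
      int e = pair_energy(seq[i], seq[k], wobble);
      if (e > 0) continue;
      int inner = (k - i > min_loop + 1) ? E[i + 1][k - 1] : 0;
      int outer = (k < j) ? E[k + 1][j] : 0;
      if (e + inner + outer == E[i][j]) {
        db[i] = '(';
        db[k] = ')';
        if (k - i > min_loop + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return List::create(_["mfe"] = (double)E[0][n - 1], _["structure"] = db);
}
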