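#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Maximum-base-pairing secondary structure with a minimum loop constraint.
// seqs: n x L matrix of 0-based letter codes; can_pair: K x K logical.
// Recurrence over intervals [i, j]:
//   M[i][j] = max( M[i+1][j],
//                  max over k: pair(i,k), k - i > hairpin_min:
//                      M[i+1][k-1] + 1 + M[k+1][j] )
// Traceback is deterministic: when pairing position i attains the optimum,
// i is paired with the smallest admissible k; otherwise i is left unpaired.
// [[Rcpp::export(rng = false)]]
CharacterVector nussinov_db(IntegerMatrix seqs, int hairpin_min,
                            LogicalMatrix can_pair) {
  const int n = seqs.nrow(), L = seqs.ncol();
  CharacterVector out(n);
  std::vector<std::vector<int> > M(L + 2, std::vector<int>(L + 2, 0));
  for (int s = 0; s < n; ++s) {
    // DP over increasing interval length
    for (int i = 0; i <= L + 1; ++i)
      for (int j = 0; j <= L + 1; ++j) M[i][j] = 0;
    for (int len = hairpin_min + 2; len <= L; ++len) {
      for (int i = 1; i + len - 1 <= L; ++i) {
        int j = i + len - 1;
        int best = M[i + 1][j];
        for (int k = i + hairpin_min + 1; k <= j; ++k) {
          if (can_pair(seqs(s, i - 1), seqs(s, k - 1))) {
            int v = M[i + 1][k - 1] + 1 + (k + 1 <= j ? M[k + 1][j] : 0);
            if (v > best) best = v;
          }
        }
        M[i][j] = best;
      }
    }
    // traceback
    std::string db(L, '.');
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(1, L));
    while (!stack.empty()) {
      int i = stack.back().first, j = stack.back().second;
      stack.pop_back();
      if (i >= j || j - i < hairpin_min + 1) continue;
      int target = M[i][j];
      if (target == 0) continue;
      bool paired = false;
      for (int k = i + hairpin_min + 1; k <= j; ++k) {
        if (can_pair(seqs(s, i - 1), seqs(s, k - 1))) {
          int v = M[i + 1][k - 1] + 1 + (k + 1 <= j ? M[k + 1][j] : 0);
          if (v == target) {
            db[i - 1] = '(';
            db[k - 1] = ')';
            stack.push_back(std::make_pair(i + 1, k - 1));
            if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
            paired = true;
            break;
          }
        }
      }
      if (!paired) stack.push_back(std::make_pair(i + 1, j));
    }
    out[s] = db;
  }
  return out;
}
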