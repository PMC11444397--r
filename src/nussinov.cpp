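#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted base-pair maximisation (Nussinov-style DP) on the DNA alphabet:
// G:C = 3, A:T = 2, G:T = 1 (arbitrary energy-like units, reported negated),
// minimum hairpin loop of 3 unpaired nucleotides. Ambiguity codes are forced
// unpaired (weight 0 against everything).

static inline int pairWeight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

static void traceback(int i, int j, const std::vector<std::vector<int>>& W,
                      const std::string& s, std::string& db) {
  if (i >= j || W[i][j] == 0) return;
  if (W[i][j] == W[i][j - 1]) { traceback(i, j - 1, W, s, db); return; }
  if (j - i >= 4) {
    int w = pairWeight(s[i], s[j]);
    int inner = (i + 1 <= j - 1) ? W[i + 1][j - 1] : 0;
    if (w > 0 && W[i][j] == inner + w) {
      db[i] = '('; db[j] = ')';
      traceback(i + 1, j - 1, W, s, db);
      return;
    }
  }
  for (int k = i; k < j; ++k) {
    if (W[i][j] == W[i][k] + W[k + 1][j]) {
      traceback(i, k, W, s, db);
      traceback(k + 1, j, W, s, db);
      return;
    }
  }
}

// [[Rcpp::export]]
List cpp_nussinov(std::string s) {
  int n = static_cast<int>(s.size());
  std::string db(n, '.');
  if (n == 0) return List::create(_["weight"] = 0, _["structure"] = db);
  std::vector<std::vector<int>> W(n, std::vector<int>(n, 0));
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = W[i][j - 1];
      int w = pairWeight(s[i], s[j]);
      if (w > 0) {
        int inner = (j - 1 >= i + 1) ? W[i + 1][j - 1] : 0;
        best = std::max(best, inner + w);
      }
      for (int k = i; k < j; ++k)
        best = std::max(best, W[i][k] + W[k + 1][j]);
      W[i][j] = best;
    }
  }
  traceback(0, n - 1, W, s, db);
  return List::create(_["weight"] = W[0][n - 1], _["structure"] = db);
}
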