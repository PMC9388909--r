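#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline bool can_pair(char a, char b, bool allow_gu) {
  // DNA alphabet; T plays the role of U
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return true;
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return true;
  if (allow_gu && ((a == 'G' && b == 'T') || (a == 'T' && b == 'G'))) return true;
  return false;
}

// Maximum number of non-crossing base pairs (Nussinov recursion) with a
// minimum hairpin loop of `min_loop` unpaired bases between paired ends.
// [[Rcpp::export(name = ".nussinov_pairs_cpp")]]
int nussinov_pairs_cpp(std::string seq, int min_loop = 3, bool allow_gu = true) {
  int n = seq.size();
  if (n == 0) return 0;
  std::vector<std::vector<int> > N(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (can_pair(seq[i], seq[k], allow_gu)) {
          int val = 1 + (k > i + 1 ? N[i + 1][k - 1] : 0) +
                    (k < j ? N[k + 1][j] : 0);
          if (val > best) best = val;
        }
      }
      N[i][j] = best;
    }
  }
  return N[0][n - 1];
}
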