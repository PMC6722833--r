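#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pseudo-energy of a base pair on the DNA alphabet (T stands for U):
// G:C = -3, A:T = -2, G:T wobble = -1 kcal/mol pseudo-units; 1 = no pair.
static inline double pair_w(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -1.0;
  return 1.0; // sentinel: not pairable
}

static const int MIN_LOOP = 3; // minimum hairpin loop length

// Maximum-weight nested (pseudoknot-free) pairing by Nussinov-style DP,
// minimizing total pseudo-energy. Traceback is deterministic: at each
// interval end, pairing is preferred over leaving the base unpaired, and
// the leftmost optimal partner wins.
// [[Rcpp::export]]
List fold_dp(std::string seq) {
  int n = seq.size();
  std::vector<std::vector<double> > E(n, std::vector<double>(n, 0.0));
  for (int len = MIN_LOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E[i][j - 1]; // j unpaired
      for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
        double w = pair_w(seq[k], seq[j]);
        if (w > 0) continue;
        double cand = w + (k > i ? E[i][k - 1] : 0.0) +
                      (k + 1 <= j - 1 ? E[k + 1][j - 1] : 0.0);
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
    if (j - i < MIN_LOOP + 1) continue;
    bool paired = false;
    for (int k = i; k <= j - MIN_LOOP - 1; ++k) { // leftmost partner first
      double w = pair_w(seq[k], seq[j]);
      if (w > 0) continue;
      double cand = w + (k > i ? E[i][k - 1] : 0.0) +
                    (k + 1 <= j - 1 ? E[k + 1][j - 1] : 0.0);
      if (cand == E[i][j]) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        stack.push_back(std::make_pair(k + 1, j - 1));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i, j - 1));
  }
  double mfe = (n > 0) ? E[0][n - 1] : 0.0;
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}
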