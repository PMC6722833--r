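#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// miRNA-target complementarity scoring. The miRNA is aligned 3'->5'
// against the target window 5'->3'. Position penalties: Watson-Crick 0,
// G:U wobble penalty_gu, mismatch penalty_mm, gap penalty_gap; penalties
// at miRNA positions seed_start..seed_end (1-based from the miRNA 5' end)
// are multiplied by seed_mult. DNA alphabet throughout (T stands for U).

static inline int pair_state(char m, char t) {
  // 2 = Watson-Crick, 1 = G:U wobble, 0 = mismatch
  if ((m == 'A' && t == 'T') || (m == 'T' && t == 'A') ||
      (m == 'G' && t == 'C') || (m == 'C' && t == 'G')) return 2;
  if ((m == 'G' && t == 'T') || (m == 'T' && t == 'G')) return 1;
  return 0;
}

struct Pen {
  double gu, mm, gap, seed_mult;
  int seed_start, seed_end;
  double mult(int pos) const { // pos: 1-based miRNA position; 0 = edge gap
    return (pos >= seed_start && pos <= seed_end) ? seed_mult : 1.0;
  }
  double base(int state) const {
    return state == 2 ? 0.0 : (state == 1 ? gu : mm);
  }
};

static const double INF = std::numeric_limits<double>::infinity();

// Full banded DP with an explicit gap-count layer; used for single-window
// scoring and alignment-string traceback.
// [[Rcpp::export]]
List comp_align_cpp(std::string mirna, std::string window,
                    double penalty_gu, double penalty_mm, double penalty_gap,
                    int seed_start, int seed_end, double seed_mult,
                    int max_gaps) {
  Pen P;
  P.gu = penalty_gu; P.mm = penalty_mm; P.gap = penalty_gap;
  P.seed_mult = seed_mult; P.seed_start = seed_start; P.seed_end = seed_end;
  int L = mirna.size(), W = window.size();
  if (std::abs(L - W) > max_gaps)
    stop("window length outside miRNA length +/- max_gaps");
  std::string m(mirna.rbegin(), mirna.rend()); // m[i] = miRNA position L-i
  int G = max_gaps;
  // D[i][j][g]: cost aligning m[0..i) with window[0..j) using g gaps
  std::vector<std::vector<std::vector<double> > > D(
      L + 1, std::vector<std::vector<double> >(
                 W + 1, std::vector<double>(G + 1, INF)));
  D[0][0][0] = 0.0;
  for (int i = 0; i <= L; ++i) {
    for (int j = 0; j <= W; ++j) {
      for (int g = 0; g <= G; ++g) {
        double cur = D[i][j][g];
        if (cur == INF) continue;
        int pos = L - i; // 1-based miRNA position of m[i] (next consumed)
        if (i < L && j < W) {
          double c = cur + P.base(pair_state(m[i], window[j])) * P.mult(pos);
          if (c < D[i + 1][j + 1][g]) D[i + 1][j + 1][g] = c;
        }
        if (g < G) {
          if (i < L) { // miRNA base opposite a gap in the target
            double c = cur + P.gap * P.mult(pos);
            if (c < D[i + 1][j][g + 1]) D[i + 1][j][g + 1] = c;
          }
          if (j < W) { // target base opposite a gap in the miRNA
            double c = cur + P.gap * (i < L ? P.mult(pos) : 1.0);
            if (c < D[i][j + 1][g + 1]) D[i][j + 1][g + 1] = c;
          }
        }
      }
    }
  }
  double best = INF;
  int bestg = 0;
  for (int g = 0; g <= G; ++g) { // fewest gaps wins ties
    if (D[L][W][g] < best) { best = D[L][W][g]; bestg = g; }
  }
  // traceback (diagonal preferred, then miRNA-gap, then target-gap)
  std::string aln;
  std::vector<int> pos_state(L, -1); // per miRNA position: 2 WC,1 GU,0 mm,-1 gap
  std::vector<int> pos_target(L, -1); // 0-based window index opposite position
  int i = L, j = W, g = bestg;
  while (i > 0 || j > 0) {
    double cur = D[i][j][g];
    if (i > 0 && j > 0) {
      int st = pair_state(m[i - 1], window[j - 1]);
      double c = P.base(st) * P.mult(L - (i - 1));
      if (D[i - 1][j - 1][g] != INF && D[i - 1][j - 1][g] + c == cur) {
        aln.push_back(st == 2 ? '|' : (st == 1 ? 'o' : '.'));
        pos_state[L - i] = st; // miRNA position L-(i-1) => index L-i (0-based pos-1)
        pos_target[L - i] = j - 1;
        --i; --j;
        continue;
      }
    }
    if (g > 0 && i > 0 &&
        D[i - 1][j][g - 1] + P.gap * P.mult(L - (i - 1)) == cur) {
      aln.push_back('-');
      pos_state[L - i] = -1;
      --i; --g;
      continue;
    }
    if (g > 0 && j > 0) {
      // mirror of the forward pass: a miRNA-side gap consumed window[j-1]
      // with the multiplier of the next miRNA position (edge gap: 1)
      double mult = (i < L) ? P.mult(L - i) : 1.0;
      if (D[i][j - 1][g - 1] + P.gap * mult == cur) {
        aln.push_back('-');
        --j; --g;
        continue;
      }
    }
    stop("traceback failed"); // unreachable
  }
  std::reverse(aln.begin(), aln.end());
  return List::create(_["score"] = best, _["alignment"] = aln,
                      _["gaps"] = bestg,
                      _["pos_state"] = IntegerVector(pos_state.begin(),
                                                     pos_state.end()),
                      _["pos_target"] = IntegerVector(pos_target.begin(),
                                                      pos_target.end()));
}

// Transcriptome scan. For <=1 gap the optimal score decomposes into
// prefix + gap + shifted suffix of ungapped alignments, so all windows are
// scored exactly in O(n * L) per transcript via prefix-cost arrays.
// Returns every window (0-based start, length, score) with score <= cutoff.
// [[Rcpp::export]]
DataFrame scan_windows_cpp(std::string mirna, std::string transcript,
                           double cutoff,
                           double penalty_gu, double penalty_mm,
                           double penalty_gap,
                           int seed_start, int seed_end, double seed_mult,
                           int max_gaps) {
  if (max_gaps > 1) stop("scan supports at most 1 gap");
  Pen P;
  P.gu = penalty_gu; P.mm = penalty_mm; P.gap = penalty_gap;
  P.seed_mult = seed_mult; P.seed_start = seed_start; P.seed_end = seed_end;
  int L = mirna.size(), n = transcript.size();
  std::string m(mirna.rbegin(), mirna.rend());
  std::vector<int> starts;
  std::vector<int> lens;
  std::vector<double> scores;
  if (n < L - max_gaps) {
    return DataFrame::create(_["start0"] = starts, _["len"] = lens,
                             _["score"] = scores);
  }
  // pref[s][c] = cost of aligning m[0..c) with transcript[s..s+c), gap-free
  // stored flat; computed lazily per start s
  std::vector<double> pref(L + 1);
  std::vector<double> prefL(L + 1), prefR(L + 1); // for shifted suffixes
  auto fill_pref = [&](int s, std::vector<double> &out) {
    out[0] = 0.0;
    for (int c = 0; c < L; ++c) {
      int t = s + c;
      if (t < 0 || t >= n) { out[c + 1] = INF; continue; }
      double cost = P.base(pair_state(m[c], transcript[t])) * P.mult(L - c);
      out[c + 1] = (out[c] == INF) ? INF : out[c] + cost;
    }
  };
  for (int s = 0; s + L - max_gaps <= n; ++s) {
    fill_pref(s, pref);
    // no gap: window [s, s+L)
    if (s + L <= n && pref[L] <= cutoff && pref[L] < INF) {
      starts.push_back(s); lens.push_back(L); scores.push_back(pref[L]);
    }
    if (max_gaps >= 1) {
      // gap in miRNA: window length L+1; cut c in 0..L, gap opposite
      // transcript[s+c]; suffix aligns m[c..L) with transcript[s+1+c..]
      if (s + L + 1 <= n) {
        fill_pref(s + 1, prefR);
        double best = INF;
        for (int c = 0; c <= L; ++c) {
          double mult = (c < L) ? P.mult(L - c) : 1.0;
          double suf = (prefR[L] == INF || prefR[c] == INF)
                           ? INF : prefR[L] - prefR[c];
          double sc = (pref[c] == INF || suf == INF)
                          ? INF : pref[c] + P.gap * mult + suf;
          if (sc < best) best = sc;
        }
        if (best <= cutoff) {
          starts.push_back(s); lens.push_back(L + 1); scores.push_back(best);
        }
      }
      // gap in target: window length L-1; miRNA base m[c] unpaired;
      // suffix aligns m[c+1..L) with transcript[s+c..]
      if (s + L - 1 <= n) {
        fill_pref(s - 1, prefL);
        double best = INF;
        for (int c = 0; c < L; ++c) {
          double mult = P.mult(L - c);
          double suf = (prefL[L] == INF || prefL[c + 1] == INF)
                           ? INF : prefL[L] - prefL[c + 1];
          double sc = (pref[c] == INF || suf == INF)
                          ? INF : pref[c] + P.gap * mult + suf;
          if (sc < best) best = sc;
        }
        if (best <= cutoff) {
          starts.push_back(s); lens.push_back(L - 1); scores.push_back(best);
        }
      }
    }
  }
  return DataFrame::create(_["start0"] = starts, _["len"] = lens,
                           _["score"] = scores);
}
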