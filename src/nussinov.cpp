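#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Base-pair maximization with stacking bonus (integer tenths of kcal/mol).
// seq codes: 0 = N / forbidden (never pairs), 1=A, 2=C, 3=G, 4=U.
// Scores: GC/CG = 30, AU/UA = 20, GU/UG = 10, stacking bonus = 10.
// Minimum hairpin loop = 3 unpaired nucleotides.

static inline int pair_score(int a, int b) {
  if (a == 0 || b == 0) return -1;
  if ((a == 3 && b == 2) || (a == 2 && b == 3)) return 30; // G-C
  if ((a == 1 && b == 4) || (a == 4 && b == 1)) return 20; // A-U
  if ((a == 3 && b == 4) || (a == 4 && b == 3)) return 10; // G-U
  return -1;
}

struct Frame { int i, j, forced; };

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(IntegerVector seq, int min_loop = 3, int stack_bonus = 10) {
  const int n = seq.size();
  if (n > 3000) stop("fold backend: window longer than 3000 nt not supported");
  if (n == 0) return List::create(_["pairing"] = IntegerVector(0),
                                  _["score"] = 0);
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = seq[i];
  const int NEG = -1000000000;
  // V[i][j]: best score with (i,j) paired; W[i][j]: best score for i..j
  std::vector<std::vector<int> > V(n, std::vector<int>(n, NEG));
  std::vector<std::vector<int> > W(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int ps = pair_score(s[i], s[j]);
      if (ps > 0) {
        int best = W[i + 1][j - 1];
        if (V[i + 1][j - 1] > NEG && V[i + 1][j - 1] + stack_bonus > best)
          best = V[i + 1][j - 1] + stack_bonus;
        V[i][j] = ps + best;
      }
      int w = W[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (V[k][j] <= NEG) continue;
        int left = (k == i) ? 0 : W[i][k - 1];
        if (left + V[k][j] > w) w = left + V[k][j];
      }
      W[i][j] = w;
    }
  }
  IntegerVector pairing(n, 0);
  std::vector<Frame> stack;
  stack.push_back(Frame{0, n - 1, 0});
  while (!stack.empty()) {
    Frame fr = stack.back();
    stack.pop_back();
    int i = fr.i, j = fr.j;
    if (i < 0 || j < 0 || j - i < min_loop + 1) continue;
    if (fr.forced) {
      pairing[i] = j + 1;
      pairing[j] = i + 1;
      int inner = V[i][j] - pair_score(s[i], s[j]);
      // prefer the stacked continuation on ties (deterministic)
      if (V[i + 1][j - 1] > NEG && V[i + 1][j - 1] + stack_bonus == inner) {
        stack.push_back(Frame{i + 1, j - 1, 1});
      } else {
        stack.push_back(Frame{i + 1, j - 1, 0});
      }
      continue;
    }
    if (W[i][j] == 0) continue;
    if (W[i][j] == W[i][j - 1]) {
      stack.push_back(Frame{i, j - 1, 0});
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (V[k][j] <= NEG) continue;
      int left = (k == i) ? 0 : W[i][k - 1];
      if (left + V[k][j] == W[i][j]) {
        if (k > i) stack.push_back(Frame{i, k - 1, 0});
        stack.push_back(Frame{k, j, 1});
        break;
      }
    }
  }
  return List::create(_["pairing"] = pairing, _["score"] = W[0][n - 1]);
}
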