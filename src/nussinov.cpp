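#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Maximum-cardinality nested base pairing (Nussinov-style DP).
//
// dp(i, j) = max( dp(i+1, j),                              [i unpaired]
//                 max_k dp(i+1, k-1) + dp(k+1, j) + 1 )    [i pairs k]
// over k in (i + min_loop, j] with (s[i], s[k]) an allowed pair.
// Tie-break is deterministic: leaving i unpaired beats pairing on equal
// score, and among equally scoring partners the smallest k wins.
//
// [[Rcpp::export]]
IntegerMatrix nussinov_pairs_cpp(std::string seq, int min_loop,
                                 CharacterVector allowed) {
  int n = seq.size();
  auto code = [](char c) -> int {
    switch (c) {
      case 'A': return 0; case 'C': return 1;
      case 'G': return 2; case 'U': return 3;
      default: return -1;
    }
  };
  bool can[4][4] = {{false}};
  for (int a = 0; a < allowed.size(); ++a) {
    std::string p = as<std::string>(allowed[a]);
    if (p.size() != 2) stop("allowed pair '%s' is not two bases", p.c_str());
    int x = code(p[0]), y = code(p[1]);
    if (x < 0 || y < 0) stop("allowed pair '%s' has a non-ACGU base",
                             p.c_str());
    can[x][y] = true;
  }
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = code(seq[i]);
    if (s[i] < 0) stop("invalid base '%c' at position %d", seq[i], i + 1);
  }
  if (n == 0) return IntegerMatrix(0, 2);
  std::vector<std::vector<int> > dp(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can[s[i]][s[k]]) continue;
        int inner = (k - 1 >= i + 1) ? dp[i + 1][k - 1] : 0;
        int outer = (k + 1 <= j) ? dp[k + 1][j] : 0;
        int sc = inner + outer + 1;
        if (sc > best) best = sc;
      }
      dp[i][j] = best;
    }
  }
  // deterministic traceback
  std::vector<std::pair<int, int> > pairs;
  std::stack<std::pair<int, int> > todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (i >= j || j - i <= min_loop) continue;
    if (dp[i][j] == dp[i + 1][j]) { // unpaired preferred on ties
      todo.push(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can[s[i]][s[k]]) continue;
      int inner = (k - 1 >= i + 1) ? dp[i + 1][k - 1] : 0;
      int outer = (k + 1 <= j) ? dp[k + 1][j] : 0;
      if (inner + outer + 1 == dp[i][j]) { // smallest k wins
        pairs.push_back(std::make_pair(i + 1, k + 1)); // 1-based
        todo.push(std::make_pair(i + 1, k - 1));
        todo.push(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  IntegerMatrix out(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    out(r, 0) = pairs[r].first;
    out(r, 1) = pairs[r].second;
  }
  return out;
}
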