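#include <Rcpp.h>
using namespace Rcpp;

// Semi-global Needleman-Wunsch on a similarity matrix with a linear gap
// penalty; terminal gaps are free. Returns the matched index pairs, strictly
// increasing in both sequences. Used by the TM-score aligner, where S holds
// the distance-derived scores 1 / (1 + (d_ij / d0)^2).

// [[Rcpp::export]]
List nw_pairs_(NumericMatrix S, double gap) {
  int n = S.nrow(), m = S.ncol();
  NumericMatrix F(n + 1, m + 1);
  IntegerMatrix tb(n + 1, m + 1); // 0 diag, 1 up (gap in B), 2 left (gap in A)

  for (int i = 0; i <= n; ++i) { F(i, 0) = 0.0; tb(i, 0) = 1; }
  for (int j = 0; j <= m; ++j) { F(0, j) = 0.0; tb(0, j) = 2; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = F(i - 1, j - 1) + S(i - 1, j - 1);
      double gi = (j == m) ? 0.0 : gap;   // free end gaps
      double gj = (i == n) ? 0.0 : gap;
      double u = F(i - 1, j) + gi;
      double l = F(i, j - 1) + gj;
      if (d >= u && d >= l)      { F(i, j) = d; tb(i, j) = 0; }
      else if (u >= l)           { F(i, j) = u; tb(i, j) = 1; }
      else                       { F(i, j) = l; tb(i, j) = 2; }
    }
  }

  std::vector<int> ai, bj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int t = tb(i, j);
    if (i > 0 && j > 0 && t == 0) { ai.push_back(i); bj.push_back(j); --i; --j; }
    else if (i > 0 && (t == 1 || j == 0)) { --i; }
    else { --j; }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());
  return List::create(_["i"] = wrap(ai), _["j"] = wrap(bj),
                      _["score"] = F(n, m));
}
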