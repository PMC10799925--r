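#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch over a residue-pair similarity matrix with a linear gap
// penalty and free terminal gaps (semiglobal), as used by TM-score style
// iterative alignment. Traceback tie-break: diagonal > up > left.
// Returns 1-based (query index, target index) pairs, strictly increasing in
// both coordinates.
// [[Rcpp::export(name = ".dp_trace")]]
IntegerMatrix dp_trace(NumericMatrix S, double gap) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix T(n + 1, m + 1); // 0 stop, 1 diag, 2 up (gap in target), 3 left

  for (int i = 1; i <= n; ++i) { H(i, 0) = 0.0; T(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { H(0, j) = 0.0; T(0, j) = 3; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      // terminal gaps (row n / column m) are free
      double up   = H(i - 1, j) + (j == m ? 0.0 : gap);
      double left = H(i, j - 1) + (i == n ? 0.0 : gap);
      double best = diag; int tb = 1;
      if (up > best)   { best = up;   tb = 2; }
      if (left > best) { best = left; tb = 3; }
      H(i, j) = best; T(i, j) = tb;
    }
  }

  std::vector<int> qi, ti;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int tb = T(i, j);
    if (tb == 1)      { qi.push_back(i); ti.push_back(j); --i; --j; }
    else if (tb == 2) { --i; }
    else              { --j; }
  }
  const int k = (int)qi.size();
  IntegerMatrix out(k, 2);
  for (int r = 0; r < k; ++r) {
    out(r, 0) = qi[k - 1 - r];
    out(r, 1) = ti[k - 1 - r];
  }
  return out;
}
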