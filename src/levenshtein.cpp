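#include <Rcpp.h>
using namespace Rcpp;

// Unit-cost edit distance between two integer-coded token sequences,
// classic O(mn) dynamic programme with a rolling row.
// [[Rcpp::export]]
int lev_dp_cpp(IntegerVector a, IntegerVector b) {
  const int m = a.size(), n = b.size();
  if (m == 0) return n;
  if (n == 0) return m;
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1] ? 1 : 0);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

static int lev_rec_impl(const int* a, int m, const int* b, int n) {
  if (m == 0) return n;
  if (n == 0) return m;
  int sub = lev_rec_impl(a + 1, m - 1, b + 1, n - 1) + (a[0] != b[0] ? 1 : 0);
  int del = lev_rec_impl(a + 1, m - 1, b, n) + 1;
  int ins = lev_rec_impl(a, m, b + 1, n - 1) + 1;
  return std::min(sub, std::min(del, ins));
}

// Memoisation-free recursive reference implementation, exponential time;
// only usable for short sequences. Kept deliberately naive so it shares no
// machinery with the dynamic programme above.
// [[Rcpp::export]]
int lev_rec_cpp(IntegerVector a, IntegerVector b) {
  if (a.size() + b.size() > 24)
    stop("reference recursion only supports short sequences");
  return lev_rec_impl(a.begin(), a.size(), b.begin(), b.size());
}
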