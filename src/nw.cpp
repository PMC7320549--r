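#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of two nucleotide strings.
// Scoring: match/mismatch/gap as passed; 'N' never matches anything,
// including another 'N'. Direction preference at equal score is
// diagonal > up > left, fixed at fill time so the traceback is
// deterministic.
//
// Returns aligned strings, the DP corner score, and match/column counts
// (matches exclude any column involving 'N').

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  int match = 1, int mismatch = -1, int gap = -2) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<char> dir((n + 1) * (m + 1));

  for (int j = 0; j <= m; ++j) { prev[j] = gap * j; dir[j] = 'L'; }
  dir[0] = '0';
  for (int i = 1; i <= n; ++i) {
    cur[0] = gap * i;
    dir[i * (m + 1)] = 'U';
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char bj = b[j - 1];
      const bool is_match = (ai == bj) && ai != 'N' && bj != 'N';
      const int sdiag = prev[j - 1] + (is_match ? match : mismatch);
      const int sup = prev[j] + gap;
      const int sleft = cur[j - 1] + gap;
      int best = sdiag; char d = 'D';
      if (sup > best) { best = sup; d = 'U'; }
      if (sleft > best) { best = sleft; d = 'L'; }
      cur[j] = best;
      dir[i * (m + 1) + j] = d;
    }
    std::swap(prev, cur);
  }
  const int score = prev[m];

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const char d = dir[i * (m + 1) + j];
    if (d == 'D') { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j; }
    else if (d == 'U') { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
    else { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int matches = 0;
  const int cols = ra.size();
  for (int k = 0; k < cols; ++k)
    if (ra[k] == rb[k] && ra[k] != '-' && ra[k] != 'N') ++matches;

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score, _["matches"] = matches,
                      _["columns"] = cols);
}
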