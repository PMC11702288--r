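#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Infix (semi-global) alignment of a short anchor against a unitig sequence:
// unit-cost Levenshtein distance of the anchor to the best-matching substring
// of the subject. Free start/end in the subject (D[0][j] = 0, minimum over the
// last row). Alongside the distance, the minimal start position of an optimal
// alignment ending at each subject position is tracked, so occurrence spans
// can be reported without a full traceback.
//
// Returns: dist; leftmost-start occurrence (ls_start, ls_end) and
// rightmost-end occurrence (re_start, re_end), both 0-based half-open,
// among all occurrences achieving the minimal distance.
// [[Rcpp::export]]
List infix_align_cpp(std::string subject, std::string pattern) {
  int m = (int)pattern.size();
  int n = (int)subject.size();
  const int INF = std::numeric_limits<int>::max() / 4;

  // rolling rows of the DP: D[i][j] edit distance of pattern[0..i) vs some
  // substring of subject ending at j; S[i][j] minimal start of such substring
  std::vector<int> Dprev(n + 1), Dcur(n + 1), Sprev(n + 1), Scur(n + 1);
  std::vector<int> Dlast(n + 1), Slast(n + 1);
  for (int j = 0; j <= n; ++j) { Dprev[j] = 0; Sprev[j] = j; }
  if (m == 0) {
    Dlast = Dprev; Slast = Sprev;
  }
  for (int i = 1; i <= m; ++i) {
    Dcur[0] = i;
    Scur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int sub = Dprev[j - 1] + (pattern[i - 1] == subject[j - 1] ? 0 : 1);
      int del = Dprev[j] + 1;      // skip a pattern base
      int ins = Dcur[j - 1] + 1;   // consume an extra subject base
      int best = sub;
      int bs = Sprev[j - 1];
      if (del < best || (del == best && Sprev[j] < bs)) { best = del; bs = Sprev[j]; }
      else if (del == best && Sprev[j] < bs) bs = Sprev[j];
      if (ins < best || (ins == best && Scur[j - 1] < bs)) { best = ins; bs = Scur[j - 1]; }
      Dcur[j] = best;
      Scur[j] = bs;
    }
    std::swap(Dprev, Dcur);
    std::swap(Sprev, Scur);
  }
  Dlast = Dprev;
  Slast = Sprev;

  int dist = INF;
  for (int j = 0; j <= n; ++j) if (Dlast[j] < dist) dist = Dlast[j];

  // leftmost-start occurrence: minimal S, tie -> smallest end
  int ls_start = -1, ls_end = -1;
  for (int j = 0; j <= n; ++j) {
    if (Dlast[j] == dist) {
      if (ls_start == -1 || Slast[j] < ls_start) { ls_start = Slast[j]; ls_end = j; }
    }
  }
  // rightmost-end occurrence: maximal end, start = its minimal start
  int re_start = -1, re_end = -1;
  for (int j = n; j >= 0; --j) {
    if (Dlast[j] == dist) { re_start = Slast[j]; re_end = j; break; }
  }

  return List::create(_["dist"] = dist,
                      _["ls_start"] = ls_start, _["ls_end"] = ls_end,
                      _["re_start"] = re_start, _["re_end"] = re_end);
}

// Batched variant over many subjects (one row per subject, same columns).
// [[Rcpp::export]]
List infix_align_batch_cpp(CharacterVector subjects, std::string pattern) {
  R_xlen_t n = subjects.size();
  IntegerVector dist(n), ls_start(n), ls_end(n), re_start(n), re_end(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    List r = infix_align_cpp(as<std::string>(subjects[i]), pattern);
    dist[i] = as<int>(r["dist"]);
    ls_start[i] = as<int>(r["ls_start"]);
    ls_end[i] = as<int>(r["ls_end"]);
    re_start[i] = as<int>(r["re_start"]);
    re_end[i] = as<int>(r["re_end"]);
  }
  return List::create(_["dist"] = dist,
                      _["ls_start"] = ls_start, _["ls_end"] = ls_end,
                      _["re_start"] = re_start, _["re_end"] = re_end);
}
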