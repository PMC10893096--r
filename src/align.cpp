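// Semi-global ("overlap") DNA alignment with linear gap cost.
// Terminal gaps are free; identity = matching columns / aligned columns
// (terminal-gap columns excluded). Ambiguity codes (incl. N) never match.

#include <Rcpp.h>
#include <vector>
#include <string>

namespace {

inline int code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // ambiguity: matches nothing
  }
}

// returns (score, matches, columns) of one optimal overlap alignment;
// traceback prefers diagonal then up then left, so results are deterministic
void overlap_align(const std::string &a, const std::string &b, double match,
                   double mismatch, double gap, double &score, int &matches,
                   int &columns) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> ca(n), cb(m);
  for (int i = 0; i < n; ++i) ca[i] = code(a[i]);
  for (int j = 0; j < m; ++j) cb[j] = code(b[j]);

  std::vector<double> S((n + 1) * (m + 1));
  const int W = m + 1;
  for (int j = 0; j <= m; ++j) S[j] = 0;
  for (int i = 1; i <= n; ++i) {
    S[i * W] = 0;
    for (int j = 1; j <= m; ++j) {
      double sub = (ca[i - 1] == cb[j - 1] && ca[i - 1] < 4) ? match : mismatch;
      double best = S[(i - 1) * W + (j - 1)] + sub;
      double up = S[(i - 1) * W + j] - gap;
      double left = S[i * W + (j - 1)] - gap;
      if (up > best) best = up;
      if (left > best) best = left;
      S[i * W + j] = best;
    }
  }
  // best end on the last row or column (free terminal gaps)
  int bi = n, bj = m;
  score = S[n * W + m];
  for (int j = 0; j <= m; ++j)
    if (S[n * W + j] > score) { score = S[n * W + j]; bi = n; bj = j; }
  for (int i = 0; i <= n; ++i)
    if (S[i * W + m] > score) { score = S[i * W + m]; bi = i; bj = m; }

  matches = 0;
  columns = 0;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    double cur = S[i * W + j];
    double sub = (ca[i - 1] == cb[j - 1] && ca[i - 1] < 4) ? match : mismatch;
    if (cur == S[(i - 1) * W + (j - 1)] + sub) {
      if (ca[i - 1] == cb[j - 1] && ca[i - 1] < 4) ++matches;
      ++columns;
      --i; --j;
    } else if (cur == S[(i - 1) * W + j] - gap) {
      ++columns;
      --i;
    } else {
      ++columns;
      --j;
    }
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".align_identity_cpp")]]
Rcpp::List align_identity_cpp(const std::string &a, const std::string &b,
                              double match = 1, double mismatch = -1,
                              double gap = 2) {
  double score;
  int matches, columns;
  overlap_align(a, b, match, mismatch, gap, score, matches, columns);
  return Rcpp::List::create(
      Rcpp::Named("identity") = columns > 0 ? (double)matches / columns : 0.0,
      Rcpp::Named("score") = score,
      Rcpp::Named("matches") = matches,
      Rcpp::Named("columns") = columns);
}

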