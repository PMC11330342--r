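#include <Rcpp.h>
using namespace Rcpp;

// Score-only Smith-Waterman with a linear gap penalty.
// Sequences are expected over {A,C,G,U}; any pair of unequal characters is a
// mismatch, equal characters are a match.
static double sw_pair(const std::string &a, const std::string &b,
                      double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double diag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up = prev[j] + gap;
      double left = cur[j - 1] + gap;
      double v = std::max(0.0, std::max(diag, std::max(up, left)));
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(std::string a, std::string b, double match,
                    double mismatch, double gap) {
  return sw_pair(a, b, match, mismatch, gap);
}

// All-pairs score matrix (symmetric, including the diagonal).
// [[Rcpp::export(name = ".sw_score_matrix_cpp")]]
NumericMatrix sw_score_matrix_cpp(CharacterVector seqs, double match,
                                  double mismatch, double gap) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double v = sw_pair(s[i], s[j], match, mismatch, gap);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
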