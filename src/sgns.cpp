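#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Skip-gram with negative sampling over a walk corpus (single-threaded,
// deterministic given seed). Noise distribution is unigram^0.75.

// [[Rcpp::export(name = ".sgns_train_cpp")]]
NumericMatrix sgns_train_cpp(List walks, int n_nodes, int dim, int window,
                             int epochs, int negative, double lr0, int seed) {
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // unigram counts
  std::vector<double> cnt(n_nodes, 0.0);
  long long corpus_tokens = 0;
  const int n_walks = walks.size();
  for (int wi = 0; wi < n_walks; ++wi) {
    IntegerVector w = walks[wi];
    corpus_tokens += w.size();
    for (int k = 0; k < w.size(); ++k) cnt[w[k] - 1] += 1.0;
  }
  // cumulative noise distribution over nodes seen in the corpus
  std::vector<double> cum(n_nodes, 0.0);
  double tot = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    if (cnt[i] > 0) tot += std::pow(cnt[i], 0.75);
    cum[i] = tot;
  }

  std::vector<double> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0);
  for (size_t k = 0; k < syn0.size(); ++k)
    syn0[k] = (unif(rng) - 0.5) / dim;

  const double total = (double)corpus_tokens * epochs;
  double processed = 0.0;
  std::vector<double> acc(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int wi = 0; wi < n_walks; ++wi) {
      IntegerVector w = walks[wi];
      const int L = w.size();
      for (int i = 0; i < L; ++i) {
        double lr = lr0 * std::max(1e-4, 1.0 - processed / total);
        processed += 1.0;
        int center = w[i] - 1;
        int b = (int)(unif(rng) * window);  // reduced window
        for (int j = i - window + b; j <= i + window - b; ++j) {
          if (j < 0 || j >= L || j == i) continue;
          int context = w[j] - 1;
          double *vin = &syn0[(size_t)center * dim];
          std::fill(acc.begin(), acc.end(), 0.0);
          for (int s = 0; s <= negative; ++s) {
            int target;
            double label;
            if (s == 0) {
              target = context;
              label = 1.0;
            } else {
              double u = unif(rng) * tot;
              target = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
              if (target >= n_nodes) target = n_nodes - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double *vout = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += vin[d] * vout[d];
            double f = 1.0 / (1.0 + std::exp(-dot));
            double g = (label - f) * lr;
            for (int d = 0; d < dim; ++d) {
              acc[d] += g * vout[d];
              vout[d] += g * vin[d];
            }
          }
          for (int d = 0; d < dim; ++d) vin[d] += acc[d];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d) out(i, d) = syn0[(size_t)i * dim + d];
  return out;
}
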