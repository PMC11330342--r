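#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Second-order biased random walks (node2vec). The graph is passed in CSR
// form: ptr (length n+1), nbr / wt (0-based neighbor ids and edge weights,
// neighbors sorted increasingly within each node for adjacency lookup).
//
// Transition out of v, having arrived from t, uses unnormalized weights
//   w(v,x)/p  if x == t,
//   w(v,x)    if x is adjacent to t,
//   w(v,x)/q  otherwise.

static inline bool is_nbr(const IntegerVector &ptr, const IntegerVector &nbr,
                          int t, int x) {
  const int *lo = nbr.begin() + ptr[t];
  const int *hi = nbr.begin() + ptr[t + 1];
  return std::binary_search(lo, hi, x);
}

// [[Rcpp::export(name = ".node2vec_walks_cpp")]]
List node2vec_walks_cpp(IntegerVector ptr, IntegerVector nbr,
                        NumericVector wt, double p, double q,
                        int walks_per_node, int walk_length, int seed) {
  const int n = ptr.size() - 1;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  List walks(n * walks_per_node);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> wbuf;
  int wi = 0;

  for (int r = 0; r < walks_per_node; ++r) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < n; ++oi) {
      int start = order[oi];
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(start);
      int prev = -1, cur = start;
      while ((int)walk.size() < walk_length) {
        int deg = ptr[cur + 1] - ptr[cur];
        if (deg == 0) break;  // isolated node: length-1 walk
        wbuf.resize(deg);
        double tot = 0.0;
        for (int k = 0; k < deg; ++k) {
          int x = nbr[ptr[cur] + k];
          double w = wt[ptr[cur] + k];
          if (prev >= 0) {
            if (x == prev) w /= p;
            else if (!is_nbr(ptr, nbr, prev, x)) w /= q;
          }
          tot += w;
          wbuf[k] = tot;
        }
        double u = unif(rng) * tot;
        int k = std::lower_bound(wbuf.begin(), wbuf.end(), u) - wbuf.begin();
        if (k >= deg) k = deg - 1;
        prev = cur;
        cur = nbr[ptr[cur] + k];
        walk.push_back(cur);
      }
      IntegerVector w1(walk.size());
      for (size_t k = 0; k < walk.size(); ++k) w1[k] = walk[k] + 1;  // 1-based
      walks[wi++] = w1;
    }
  }
  return walks;
}
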