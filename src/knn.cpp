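#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Brute-force k-nearest-neighbour classification with deterministic
// tie-breaking (nearer neighbour first, lower training index on exact
// distance ties, lowest class code on vote ties).  Codes are 1-based class
// indices; weighted = inverse-distance vote weighting.
// [[Rcpp::export(name = ".knn_predict_codes")]]
IntegerVector knn_predict_codes(NumericMatrix Xtr, IntegerVector ytr,
                                NumericMatrix Xte, int k, bool weighted,
                                int n_classes) {
  const int ntr = Xtr.nrow(), nte = Xte.nrow(), d = Xtr.ncol();
  if (k > ntr) k = ntr;
  if (k < 1) k = 1;
  IntegerVector out(nte);
  std::vector<std::pair<double, int> > dist(ntr);
  std::vector<double> votes(n_classes);

  // row-major copies so the inner distance loop walks contiguous memory
  std::vector<double> tr(static_cast<size_t>(ntr) * d), te(static_cast<size_t>(nte) * d);
  for (int j = 0; j < ntr; ++j)
    for (int f = 0; f < d; ++f) tr[static_cast<size_t>(j) * d + f] = Xtr(j, f);
  for (int i = 0; i < nte; ++i)
    for (int f = 0; f < d; ++f) te[static_cast<size_t>(i) * d + f] = Xte(i, f);

  for (int i = 0; i < nte; ++i) {
    const double *ti = &te[static_cast<size_t>(i) * d];
    for (int j = 0; j < ntr; ++j) {
      const double *tj = &tr[static_cast<size_t>(j) * d];
      double s = 0.0;
      for (int f = 0; f < d; ++f) {
        const double diff = ti[f] - tj[f];
        s += diff * diff;
      }
      dist[j] = std::make_pair(s, j);
    }
    std::partial_sort(dist.begin(), dist.begin() + k, dist.end());
    std::fill(votes.begin(), votes.end(), 0.0);
    for (int t = 0; t < k; ++t) {
      const double w = weighted
        ? 1.0 / (std::sqrt(dist[t].first) + 1e-12)
        : 1.0;
      votes[ytr[dist[t].second] - 1] += w;
    }
    int best = 0;
    for (int c = 1; c < n_classes; ++c) {
      if (votes[c] > votes[best]) best = c;
    }
    out[i] = best + 1;
  }
  return out;
}
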