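#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// K-nearest-neighbour regression: mean target of the k nearest training rows
// by Euclidean distance; exact distance ties are broken in favour of the
// lowest training-row index.  Small k uses an insertion top-k pass; large k
// falls back to nth_element on (distance, index) pairs.
// [[Rcpp::export]]
NumericVector knn_predict_cpp(NumericMatrix train_X, NumericVector train_y,
                              NumericMatrix query, int k) {
  const int n = train_X.nrow(), p = train_X.ncol(), m = query.nrow();
  NumericVector out(m);
  const double *X = REAL(train_X), *Q = REAL(query);

  if (k <= 32) {
    std::vector<double> bestD(k);
    std::vector<int> bestI(k);
    for (int q = 0; q < m; ++q) {
      int filled = 0;
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < p; ++j) {
          const double diff = X[i + (R_xlen_t)j * n] - Q[q + (R_xlen_t)j * m];
          s += diff * diff;
        }
        if (filled == k && s >= bestD[k - 1]) continue;  // ties lose to earlier i
        int pos = (filled < k) ? filled : k - 1;
        while (pos > 0 && bestD[pos - 1] > s) {
          bestD[pos] = bestD[pos - 1];
          bestI[pos] = bestI[pos - 1];
          --pos;
        }
        bestD[pos] = s;
        bestI[pos] = i;
        if (filled < k) ++filled;
      }
      double acc = 0.0;
      for (int i = 0; i < k; ++i) acc += train_y[bestI[i]];
      out[q] = acc / k;
    }
  } else {
    std::vector<std::pair<double, int> > d(n);
    for (int q = 0; q < m; ++q) {
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < p; ++j) {
          const double diff = X[i + (R_xlen_t)j * n] - Q[q + (R_xlen_t)j * m];
          s += diff * diff;
        }
        d[i] = std::make_pair(s, i);
      }
      std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
      double acc = 0.0;
      for (int i = 0; i < k; ++i) acc += train_y[d[i].second];
      out[q] = acc / k;
    }
  }
  return out;
}
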