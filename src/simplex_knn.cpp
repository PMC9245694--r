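#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exponentially weighted nearest-neighbour projection.
// D(i, j): distance from prediction row i to library row j.
// lib, pred: time indices (1-based) of library and prediction rows.
// y: target series aligned with time indices; k: neighbours; r: exclusion
// radius in time steps (library rows within r of the prediction row are
// skipped; r < 0 disables the guard). Ties in distance break toward the
// earlier library time.
// [[Rcpp::export(name = ".simplex_knn_cpp")]]
NumericVector simplex_knn_cpp(NumericMatrix D, IntegerVector lib,
                              IntegerVector pred, NumericVector y,
                              int k, int r) {
  const int np = pred.size(), nl = lib.size();
  NumericVector yhat(np, NA_REAL);
  std::vector<int> idx;
  idx.reserve(nl);
  for (int i = 0; i < np; ++i) {
    idx.clear();
    for (int j = 0; j < nl; ++j) {
      if (std::abs(lib[j] - pred[i]) > r) idx.push_back(j);
    }
    if ((int)idx.size() < k) continue;
    const double *di = &D(i, 0);
    const int stride = D.nrow();
    auto cmp = [&](int a, int b) {
      double da = di[(size_t)a * stride], db = di[(size_t)b * stride];
      if (da != db) return da < db;
      return lib[a] < lib[b];
    };
    std::partial_sort(idx.begin(), idx.begin() + k, idx.end(), cmp);
    double dmin = di[(size_t)idx[0] * stride];
    double sw = 0.0, sy = 0.0;
    for (int m = 0; m < k; ++m) {
      double d = di[(size_t)idx[m] * stride];
      double w;
      if (dmin > 0.0) {
        w = std::exp(-d / dmin);
      } else {
        w = (d == 0.0) ? 1.0 : 0.0;
      }
      sw += w;
      sy += w * y[lib[idx[m]] - 1];
    }
    if (sw > 0.0) yhat[i] = sy / sw;
  }
  return yhat;
}
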