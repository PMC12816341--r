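#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Chebyshev (maximum-norm) neighbour primitives for the shared-radius
// nearest-neighbour entropy estimators.
//
// Points are scanned in order of their first coordinate: any point within
// Chebyshev distance r of point i must lie within r of it along the first
// coordinate, so the scan can stop once that coordinate drifts beyond the
// current cap.  This prunes the O(N^2) brute force to near-linear work per
// query for the small radii typical of k-NN estimation.

static inline double cheb_dist_row(const double *X, int n, int d,
                                   int i, int j, double cap) {
  double m = 0.0;
  for (int c = 0; c < d; ++c) {
    double v = X[i + (size_t)c * n] - X[j + (size_t)c * n];
    if (v < 0) v = -v;
    if (v > m) {
      m = v;
      if (m >= cap) return m;  // early exit: already past the cap
    }
  }
  return m;
}

static std::vector<int> order_by_first_col(const NumericMatrix &X) {
  const int n = X.nrow();
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  const double *x0 = &X(0, 0);
  std::sort(ord.begin(), ord.end(),
            [x0](int a, int b) { return x0[a] < x0[b]; });
  return ord;
}

// Distance to the k-th nearest neighbour (self excluded) of every point.
// [[Rcpp::export(name = ".knn_kth_dist")]]
NumericVector knn_kth_dist(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < N");
  const double *xp = &X(0, 0);
  const std::vector<int> ord = order_by_first_col(X);
  std::vector<int> pos(n);  // position of each point in the sorted order
  for (int s = 0; s < n; ++s) pos[ord[s]] = s;
  NumericVector out(n);
  std::vector<double> heap;  // max-heap of the k smallest distances so far
  heap.reserve(k + 1);
  for (int i = 0; i < n; ++i) {
    heap.clear();
    double cap = R_PosInf;
    const double xi0 = xp[i];
    int lo = pos[i] - 1, hi = pos[i] + 1;
    while (lo >= 0 || hi < n) {
      int j;
      // take next candidate from the side closer in the first coordinate
      bool take_lo;
      if (lo >= 0 && hi < n)
        take_lo = (xi0 - xp[ord[lo]]) <= (xp[ord[hi]] - xi0);
      else
        take_lo = (lo >= 0);
      if (take_lo) {
        j = ord[lo];
        if (xi0 - xp[j] >= cap) { lo = -1; if (hi >= n) break; continue; }
        --lo;
      } else {
        j = ord[hi];
        if (xp[j] - xi0 >= cap) { hi = n; if (lo < 0) break; continue; }
        ++hi;
      }
      double dij = cheb_dist_row(xp, n, d, i, j, cap);
      if ((int)heap.size() < k) {
        heap.push_back(dij);
        std::push_heap(heap.begin(), heap.end());
        if ((int)heap.size() == k) cap = heap.front();
      } else if (dij < heap.front()) {
        std::pop_heap(heap.begin(), heap.end());
        heap.back() = dij;
        std::push_heap(heap.begin(), heap.end());
        cap = heap.front();
      }
    }
    out[i] = heap.front();
  }
  return out;
}

// Number of points strictly within radius[i] of point i (self excluded),
// in the subspace given by the columns of X.
// [[Rcpp::export(name = ".knn_range_count")]]
IntegerVector knn_range_count(NumericMatrix X, NumericVector radius) {
  const int n = X.nrow(), d = X.ncol();
  if (radius.size() != n) stop("radius must have one entry per row");
  const double *xp = &X(0, 0);
  const std::vector<int> ord = order_by_first_col(X);
  std::vector<int> pos(n);
  for (int s = 0; s < n; ++s) pos[ord[s]] = s;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double r = radius[i];
    const double xi0 = xp[i];
    int cnt = 0;
    for (int s = pos[i] - 1; s >= 0; --s) {
      int j = ord[s];
      if (xi0 - xp[j] >= r) break;
      if (cheb_dist_row(xp, n, d, i, j, r) < r) ++cnt;
    }
    for (int s = pos[i] + 1; s < n; ++s) {
      int j = ord[s];
      if (xp[j] - xi0 >= r) break;
      if (cheb_dist_row(xp, n, d, i, j, r) < r) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}
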