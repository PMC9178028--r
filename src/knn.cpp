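#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact k-nearest neighbours, Euclidean, ties toward the smaller index.
// Returns an m x k matrix of 1-based neighbour indices, nearest first.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(const NumericMatrix& coords, const int k) {
  const int m = coords.nrow(), d = coords.ncol();
  if (m <= k) stop("need more points than k");
  IntegerMatrix nn(m, k);
  std::vector<std::pair<double, int> > cand(m);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = coords(i, c) - coords(j, c);
        s += diff * diff;
      }
      cand[j] = std::make_pair(j == i ? R_PosInf : s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) nn(i, j) = cand[j].second + 1;
  }
  return nn;
}

// k smallest entries per row of a precomputed squared-distance matrix
// (diagonal treated as +Inf); ties toward the smaller index.
// [[Rcpp::export]]
IntegerMatrix cpp_knn_from_dist(const NumericMatrix& D, const int k) {
  const int m = D.nrow();
  if (m <= k) stop("need more points than k");
  IntegerMatrix nn(m, k);
  std::vector<std::pair<double, int> > cand(m);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j)
      cand[j] = std::make_pair(j == i ? R_PosInf : D(j, i), j);
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) nn(i, j) = cand[j].second + 1;
  }
  return nn;
}

// column-blockwise max over k stacked m-row slabs: z is (m*k) x d with
// slab j holding neighbour j of every point; returns max value and the
// winning slab index per (point, channel)
// [[Rcpp::export]]
List cpp_edge_max(const NumericMatrix& z, const int m, const int k) {
  const int d = z.ncol();
  NumericMatrix best(m, d);
  IntegerMatrix arg(m, d);
  for (int c = 0; c < d; ++c) {
    for (int i = 0; i < m; ++i) { best(i, c) = z(i, c); arg(i, c) = 1; }
    for (int j = 1; j < k; ++j) {
      const int off = j * m;
      for (int i = 0; i < m; ++i) {
        const double v = z(off + i, c);
        if (v > best(i, c)) { best(i, c) = v; arg(i, c) = j + 1; }
      }
    }
  }
  return List::create(_["best"] = best, _["argmax"] = arg);
}

// Index (1-based) of the nearest row of `ref` for each row of `query`;
// ties toward the smaller index.
// [[Rcpp::export]]
IntegerVector cpp_nearest(const NumericMatrix& query,
                          const NumericMatrix& ref) {
  const int nq = query.nrow(), nr = ref.nrow(), d = query.ncol();
  if (ref.ncol() != d) stop("dimension mismatch");
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int arg = 0;
    for (int j = 0; j < nr; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = query(i, c) - ref(j, c);
        s += diff * diff;
      }
      if (s < best) { best = s; arg = j; }
    }
    out[i] = arg + 1;
  }
  return out;
}
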