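#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Disjoint-set forest with path halving + union by rank.
static int ds_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

//' @title Component-merge heights of the distance filtration
//' @description Kruskal's algorithm on the complete weighted graph given by a
//'   symmetric distance matrix. The n-1 edge weights at which two components
//'   join (equivalently, the minimum-spanning-tree edge weights / single-
//'   linkage dendrogram heights) are returned in non-decreasing order. Ties
//'   are processed in stable (i, j) index order; tie order cannot change the
//'   merge heights, only which tied edge is recorded as the merger.
//' @keywords internal
// [[Rcpp::export(name = ".mst_merge_heights")]]
NumericVector mst_merge_heights(NumericMatrix d) {
  const int n = d.nrow();
  if (n != d.ncol()) stop("distance matrix must be square");
  if (n < 1) stop("empty distance matrix");
  if (n == 1) return NumericVector(0);

  const R_xlen_t ne = (R_xlen_t)n * (n - 1) / 2;
  std::vector<double> w(ne);
  std::vector<int> ei(ne), ej(ne);
  R_xlen_t k = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++k) {
      double v = d(i, j);
      if (ISNAN(v)) stop("NaN distance between nodes %d and %d", i + 1, j + 1);
      w[k] = v; ei[k] = i; ej[k] = j;
    }
  }

  std::vector<R_xlen_t> ord(ne);
  std::iota(ord.begin(), ord.end(), (R_xlen_t)0);
  std::sort(ord.begin(), ord.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (w[a] != w[b]) return w[a] < w[b];
    if (ei[a] != ei[b]) return ei[a] < ei[b];
    return ej[a] < ej[b];
  });

  std::vector<int> parent(n), rank_(n, 0);
  std::iota(parent.begin(), parent.end(), 0);

  NumericVector merges(n - 1);
  int found = 0;
  for (R_xlen_t t = 0; t < ne && found < n - 1; ++t) {
    const R_xlen_t e = ord[t];
    int ra = ds_find(parent, ei[e]);
    int rb = ds_find(parent, ej[e]);
    if (ra == rb) continue;
    if (rank_[ra] < rank_[rb]) std::swap(ra, rb);
    parent[rb] = ra;
    if (rank_[ra] == rank_[rb]) ++rank_[ra];
    merges[found++] = w[e];
  }
  return merges;
}

//' @title Seeded pairwise transpositions of a weight vector
//' @description Applies nswaps random transpositions to a copy of w, drawing
//'   index pairs from R's RNG stream (so results are governed by set.seed()).
//' @keywords internal
// [[Rcpp::export(name = ".transpose_weights")]]
NumericVector transpose_weights(NumericVector w, int nswaps) {
  const R_xlen_t m = w.size();
  if (m < 2) return clone(w);
  NumericVector out = clone(w);
  RNGScope scope;
  for (int s = 0; s < nswaps; ++s) {
    R_xlen_t a = (R_xlen_t)(unif_rand() * m);
    R_xlen_t b = (R_xlen_t)(unif_rand() * m);
    if (a >= m) a = m - 1;
    if (b >= m) b = m - 1;
    std::swap(out[a], out[b]);
  }
  return out;
}
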