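// k-medoids clustering of tag coverage vectors by local search: starting from
// a random choice of S medoids, repeatedly apply the best cost-improving
// (medoid, non-medoid) swap until no swap improves the total (weighted)
// distance of points to their nearest medoid. Points may carry integer
// weights: identical coverage vectors are collapsed upstream and re-expanded
// after clustering, which leaves the solution unchanged but shrinks n.
//
// Each candidate replacement point h is evaluated against all S removals in
// one pass over the points using cached nearest/second-nearest distances
// (the FastPAM decomposition), so a full swap round costs O(n^2 d).

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static inline double dist_ld(const NumericMatrix& X, int a, int b, int metric) {
  const int d = X.ncol();
  double s = 0.0;
  if (metric == 0) {  // L1
    for (int j = 0; j < d; ++j) s += std::fabs(X(a, j) - X(b, j));
  } else {  // L2
    for (int j = 0; j < d; ++j) {
      const double t = X(a, j) - X(b, j);
      s += t * t;
    }
    s = std::sqrt(s);
  }
  return s;
}

struct Cache {
  std::vector<double> d1, d2;  // nearest / second-nearest medoid distance
  std::vector<int> a1;         // index (into medoid list) of nearest medoid
};

static double recache(const NumericMatrix& X, const NumericVector& w,
                      const std::vector<int>& med, int metric, Cache& c) {
  const int n = X.nrow(), S = (int)med.size();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double b1 = std::numeric_limits<double>::infinity(), b2 = b1;
    int wh = -1;
    for (int k = 0; k < S; ++k) {
      const double d = dist_ld(X, i, med[k], metric);
      if (d < b1) { b2 = b1; b1 = d; wh = k; }
      else if (d < b2) { b2 = d; }
    }
    c.d1[i] = b1; c.d2[i] = b2; c.a1[i] = wh;
    total += w[i] * b1;
  }
  return total;
}

// starts: n_starts x S matrix of 1-based initial medoid row indices.
// [[Rcpp::export]]
List kmedoids_cpp(NumericMatrix X, NumericVector w, IntegerMatrix starts,
                  int metric, int max_iter) {
  const int n = X.nrow(), S = starts.ncol(), n_starts = starts.nrow();
  double best_cost = std::numeric_limits<double>::infinity();
  std::vector<int> best_med;

  std::vector<double> removal(S);
  for (int s0 = 0; s0 < n_starts; ++s0) {
    std::vector<int> med(S);
    for (int k = 0; k < S; ++k) med[k] = starts(s0, k) - 1;
    std::vector<char> is_med(n, 0);
    for (int k = 0; k < S; ++k) is_med[med[k]] = 1;

    Cache c;
    c.d1.resize(n); c.d2.resize(n); c.a1.resize(n);
    double cost = recache(X, w, med, metric, c);

    for (int it = 0; it < max_iter; ++it) {
      double best_delta = -1e-12;
      int best_k = -1, best_h = -1;
      for (int h = 0; h < n; ++h) {
        if (is_med[h]) continue;
        // one pass over points: 'acc' accumulates the gain common to every
        // removal, 'removal[k]' the correction for removing point i's own
        // nearest medoid k
        double acc = 0.0;
        std::fill(removal.begin(), removal.end(), 0.0);
        for (int i = 0; i < n; ++i) {
          const double dh = dist_ld(X, i, h, metric);
          const double common = std::min(dh - c.d1[i], 0.0);
          acc += w[i] * common;
          removal[c.a1[i]] +=
              w[i] * ((std::min(dh, c.d2[i]) - c.d1[i]) - common);
        }
        for (int k = 0; k < S; ++k) {
          const double delta = acc + removal[k];
          if (delta < best_delta) { best_delta = delta; best_k = k; best_h = h; }
        }
      }
      if (best_k < 0) break;  // local optimum: no improving swap
      is_med[med[best_k]] = 0;
      med[best_k] = best_h;
      is_med[best_h] = 1;
      cost = recache(X, w, med, metric, c);
    }

    if (cost < best_cost) { best_cost = cost; best_med = med; }
  }

  // final assignment for the best start
  Cache c;
  c.d1.resize(n); c.d2.resize(n); c.a1.resize(n);
  recache(X, w, best_med, metric, c);
  IntegerVector medoids(S), labels(n);
  for (int k = 0; k < S; ++k) medoids[k] = best_med[k] + 1;
  for (int i = 0; i < n; ++i) labels[i] = c.a1[i] + 1;
  return List::create(_["medoids"] = medoids, _["labels"] = labels,
                      _["cost"] = best_cost);
}
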