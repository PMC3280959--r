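// Greedy maximal independent set (tag selection), tag affiliation, and
// per-tag coverage vectors on the read-overlap graph.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// CSR adjacency from an undirected edge list (1-based vertices)
static void build_adj(int n, const IntegerVector& from, const IntegerVector& to,
                      std::vector<int>& ptr, std::vector<int>& adj) {
  const int m = from.size();
  ptr.assign(n + 1, 0);
  adj.assign(2 * (size_t)m, 0);
  for (int e = 0; e < m; ++e) {
    ++ptr[from[e]];  // degree of 0-based vertex from[e]-1 lands in slot u+1
    ++ptr[to[e]];
  }
  for (int v = 1; v <= n; ++v) ptr[v] += ptr[v - 1];
  // ptr[u] is now the start of 0-based vertex u's segment, ptr[u+1] its end
  std::vector<int> cur(ptr.begin(), ptr.end() - 1);
  for (int e = 0; e < m; ++e) {
    adj[cur[from[e] - 1]++] = to[e] - 1;
    adj[cur[to[e] - 1]++] = from[e] - 1;
  }
}

// Scan vertices in 'order'; a vertex becomes a tag when no neighbour is
// already tagged. Every non-tag is then affiliated with its earliest-scanned
// tagged neighbour. Returns tag flags and affiliation (1-based read index of
// the owning tag; tags map to themselves).
// [[Rcpp::export]]
List greedy_mis_cpp(int n, IntegerVector from, IntegerVector to,
                    IntegerVector order) {
  std::vector<int> ptr, adj;
  build_adj(n, from, to, ptr, adj);

  std::vector<int> rank(n);
  for (int i = 0; i < n; ++i) rank[order[i] - 1] = i;

  std::vector<char> tag(n, 0);
  for (int i = 0; i < n; ++i) {
    const int v = order[i] - 1;
    bool free_v = true;
    for (int t = ptr[v]; t < ptr[v + 1]; ++t)
      if (tag[adj[t]]) { free_v = false; break; }
    if (free_v) tag[v] = 1;
  }

  IntegerVector affil(n);
  LogicalVector is_tag(n);
  for (int v = 0; v < n; ++v) {
    is_tag[v] = (bool)tag[v];
    if (tag[v]) {
      affil[v] = v + 1;
    } else {
      int best = -1, bestrank = n;
      for (int t = ptr[v]; t < ptr[v + 1]; ++t) {
        const int u = adj[t];
        if (tag[u] && rank[u] < bestrank) { best = u; bestrank = rank[u]; }
      }
      affil[v] = best + 1;  // 0 would mean an unaffiliated non-tag (impossible
                            // for a maximal independent set)
    }
  }
  return List::create(_["is_tag"] = is_tag, _["affiliation"] = affil);
}

// coverage[t, s] = number of graph neighbours of tag t from sample s, plus one
// for the tag itself in its own sample.
// [[Rcpp::export]]
IntegerMatrix coverage_cpp(int n, IntegerVector from, IntegerVector to,
                           IntegerVector tags, IntegerVector sample_of,
                           int n_samples) {
  std::vector<int> ptr, adj;
  build_adj(n, from, to, ptr, adj);
  const int nt = tags.size();
  IntegerMatrix cov(nt, n_samples);
  for (int i = 0; i < nt; ++i) {
    const int t = tags[i] - 1;
    cov(i, sample_of[t] - 1) += 1;  // self
    for (int e = ptr[t]; e < ptr[t + 1]; ++e)
      cov(i, sample_of[adj[e]] - 1) += 1;
  }
  return cov;
}
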