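#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Shortest-path accumulation kernels shared by the load and percolation
// centralities. Graphs arrive as 0-based adjacency lists.

// Load centrality (Goh's flow betweenness): every node sends one unit to
// every other node; at each hop the unit splits EVENLY among the neighbours
// one step closer to the source (not proportionally to path counts, which is
// what distinguishes load from betweenness on non-tree graphs). Returns
// sum over sources s != v of (load at v - 1), halved for the undirected
// double count.
// [[Rcpp::export]]
NumericVector cpp_load_centrality(List adj, int n) {
  std::vector< std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i) nbr[i] = as< std::vector<int> >(adj[i]);
  NumericVector cent(n);
  std::vector<int> dist(n), order;
  order.reserve(n);
  std::vector<double> load(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    order.clear();
    std::queue<int> q;
    dist[s] = 0; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order.push_back(v);
      for (int w : nbr[v]) if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
    }
    std::fill(load.begin(), load.end(), 1.0);
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int v = order[i];
      int npred = 0;
      for (int w : nbr[v]) if (dist[w] == dist[v] - 1) ++npred;
      double share = load[v] / npred;
      for (int w : nbr[v]) if (dist[w] == dist[v] - 1) load[w] += share;
    }
    for (int v = 0; v < n; ++v)
      if (v != s && dist[v] >= 0) cent[v] += load[v] - 1.0;
  }
  for (int v = 0; v < n; ++v) cent[v] /= 2.0;
  return cent;
}

// Brandes dependency accumulation with per-source weights:
// returns  dep[v] = sum_s w_s * delta_s(v),  where
// delta_s(v) = sum_{t != s} sigma_st(v) / sigma_st.
// With w == 1 this is twice the raw undirected betweenness.
// [[Rcpp::export]]
NumericVector cpp_weighted_dependency(List adj, int n, NumericVector w) {
  std::vector< std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i) nbr[i] = as< std::vector<int> >(adj[i]);
  NumericVector dep(n);
  std::vector<int> dist(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<int> order;
  order.reserve(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    order.clear();
    std::queue<int> q;
    dist[s] = 0; sigma[s] = 1.0; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order.push_back(v);
      for (int t : nbr[v]) {
        if (dist[t] < 0) { dist[t] = dist[v] + 1; q.push(t); }
        if (dist[t] == dist[v] + 1) sigma[t] += sigma[v];
      }
    }
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int v = order[i];
      for (int t : nbr[v]) {
        if (dist[t] == dist[v] - 1)
          delta[t] += sigma[t] / sigma[v] * (1.0 + delta[v]);
      }
      if (v != s) dep[v] += w[s] * delta[v];
    }
  }
  return dep;
}
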