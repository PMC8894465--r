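#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Degree-preserving double-edge-swap rewiring (randomized or latticized null),
// optionally rejecting swaps that disconnect the graph. Uses R's RNG so
// set.seed() on the R side makes it reproducible.
//
// Randomized: any valid swap (no self-loop, no multi-edge) is accepted.
// Latticized: a valid swap is accepted only if it does not increase the total
// ring distance sum(min(|i-j|, N-|i-j|)) of the swapped edges under the fixed
// circular node ordering (the BCT latmio acceptance rule).

static bool connected_all(const std::vector<std::unordered_set<int>> &adj, int n) {
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  stack.push_back(0);
  seen[0] = 1;
  int count = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    for (int w : adj[v]) {
      if (!seen[w]) { seen[w] = 1; ++count; stack.push_back(w); }
    }
  }
  return count == n;
}

static bool share_neighbor(const std::vector<std::unordered_set<int>> &adj,
                           int u, int v) {
  const std::unordered_set<int> &small =
      adj[u].size() <= adj[v].size() ? adj[u] : adj[v];
  const std::unordered_set<int> &large =
      adj[u].size() <= adj[v].size() ? adj[v] : adj[u];
  for (int w : small)
    if (large.count(w)) return true;
  return false;
}

static inline int ring_dist(int i, int j, int n) {
  int d = i > j ? i - j : j - i;
  return d < n - d ? d : n - d;
}

// [[Rcpp::export]]
IntegerMatrix rewire_cpp(IntegerMatrix edges, int n_nodes, double n_attempts,
                         bool lattice, bool require_connected) {
  const int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  std::vector<std::unordered_set<int>> adj(n_nodes);
  for (int e = 0; e < m; ++e) {
    ea[e] = edges(e, 0) - 1;
    eb[e] = edges(e, 1) - 1;
    adj[ea[e]].insert(eb[e]);
    adj[eb[e]].insert(ea[e]);
  }

  long attempts = (long)(n_attempts + 0.5);
  for (long t = 0; t < attempts; ++t) {
    int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
    int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == c || a == d || b == c || b == d) continue;
    // proposed: (a,d) and (c,b)
    if (adj[a].count(d) || adj[c].count(b)) continue;
    if (lattice) {
      int before = ring_dist(a, b, n_nodes) + ring_dist(c, d, n_nodes);
      int after = ring_dist(a, d, n_nodes) + ring_dist(c, b, n_nodes);
      if (after > before) continue;
    }
    // apply
    adj[a].erase(b); adj[b].erase(a);
    adj[c].erase(d); adj[d].erase(c);
    adj[a].insert(d); adj[d].insert(a);
    adj[c].insert(b); adj[b].insert(c);
    // removing a non-bridge edge cannot disconnect: if the endpoints of both
    // removed edges still share a neighbor, skip the full BFS
    bool safe = share_neighbor(adj, a, b) && share_neighbor(adj, c, d);
    if (require_connected && !safe && !connected_all(adj, n_nodes)) {
      adj[a].erase(d); adj[d].erase(a);
      adj[c].erase(b); adj[b].erase(c);
      adj[a].insert(b); adj[b].insert(a);
      adj[c].insert(d); adj[d].insert(c);
      continue;
    }
    ea[e1] = a; eb[e1] = d;
    ea[e2] = c; eb[e2] = b;
  }

  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    int i = ea[e] + 1, j = eb[e] + 1;
    out(e, 0) = i < j ? i : j;
    out(e, 1) = i < j ? j : i;
  }
  return out;
}
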