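#include <Rcpp.h>
#include <algorithm>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Link-community clustering of an undirected simple graph.
//
// Edges are clustered by single-linkage agglomeration on the Ahn-Bagrow-Lehmann
// similarity: for two edges sharing exactly one node k, with non-shared
// endpoints i and j, sim = |n+(i) & n+(j)| / |n+(i) | n+(j)| where n+(x) is the
// inclusive neighborhood {x} + neighbors(x). Non-adjacent edge pairs have
// similarity 0 and can only end up together through chains. Because every
// positive-similarity pair is adjacent, single linkage reduces to Kruskal-style
// union-find over the adjacent-pair list sorted by descending similarity
// (ties: lexicographic edge order). The returned cut maximizes the partition
// density D = (2/m) * sum_c m_c*(m_c-(n_c-1)) / ((n_c-2)(n_c-1)), with the
// contribution of communities spanning n_c = 2 nodes defined as 0; ties
// between cuts are broken toward fewer communities (the later cut).

struct EdgePair {
  double sim;
  int e1, e2; // e1 < e2, 0-based canonical edge ids
};

static inline double contribution(double mc, double nc) {
  if (nc <= 2.0) return 0.0;
  return mc * (mc - (nc - 1.0)) / ((nc - 2.0) * (nc - 1.0));
}

struct DSU {
  std::vector<int> parent;
  std::vector<int> m_c;                           // edge count per root
  std::vector<std::unordered_set<int>> nodes;     // node set per root
  DSU(int m, const IntegerMatrix &edges) : parent(m), m_c(m, 1), nodes(m) {
    for (int i = 0; i < m; ++i) {
      parent[i] = i;
      nodes[i].insert(edges(i, 0));
      nodes[i].insert(edges(i, 1));
    }
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  // returns delta in sum of contributions, or NA if already same cluster
  bool unite(int x, int y, double &delta) {
    int rx = find(x), ry = find(y);
    if (rx == ry) return false;
    // small-to-large on node sets
    if (nodes[rx].size() < nodes[ry].size()) std::swap(rx, ry);
    double before = contribution(m_c[rx], nodes[rx].size()) +
                    contribution(m_c[ry], nodes[ry].size());
    for (int v : nodes[ry]) nodes[rx].insert(v);
    nodes[ry].clear();
    m_c[rx] += m_c[ry];
    parent[ry] = rx;
    delta = contribution(m_c[rx], nodes[rx].size()) - before;
    return true;
  }
};

// [[Rcpp::export]]
List lc_cover_cpp(IntegerMatrix edges, int n_nodes) {
  const int m = edges.nrow();
  if (m < 1) stop("graph has no edges");

  std::vector<std::vector<int>> nbr(n_nodes), inc(n_nodes);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    nbr[a].push_back(b); nbr[b].push_back(a);
    inc[a].push_back(e); inc[b].push_back(e);
  }
  std::vector<std::vector<int>> nplus(n_nodes);
  for (int v = 0; v < n_nodes; ++v) {
    nplus[v] = nbr[v];
    nplus[v].push_back(v);
    std::sort(nplus[v].begin(), nplus[v].end());
  }

  std::vector<EdgePair> pairs;
  for (int k = 0; k < n_nodes; ++k) {
    const std::vector<int> &ik = inc[k];
    const int d = (int)ik.size();
    for (int x = 0; x < d; ++x) {
      for (int y = x + 1; y < d; ++y) {
        int ea = ik[x], eb = ik[y];
        int i = (edges(ea, 0) - 1 == k) ? edges(ea, 1) - 1 : edges(ea, 0) - 1;
        int j = (edges(eb, 0) - 1 == k) ? edges(eb, 1) - 1 : edges(eb, 0) - 1;
        // sorted intersection size
        const std::vector<int> &A = nplus[i], &B = nplus[j];
        size_t p = 0, q = 0; int inter = 0;
        while (p < A.size() && q < B.size()) {
          if (A[p] < B[q]) ++p;
          else if (A[p] > B[q]) ++q;
          else { ++inter; ++p; ++q; }
        }
        double uni = (double)A.size() + (double)B.size() - inter;
        EdgePair ep;
        ep.sim = inter / uni;
        ep.e1 = std::min(ea, eb);
        ep.e2 = std::max(ea, eb);
        pairs.push_back(ep);
      }
    }
  }
  std::sort(pairs.begin(), pairs.end(), [](const EdgePair &a, const EdgePair &b) {
    if (a.sim != b.sim) return a.sim > b.sim;
    if (a.e1 != b.e1) return a.e1 < b.e1;
    return a.e2 < b.e2;
  });

  // Pass 1: walk similarity levels, tracking D after each completed level.
  DSU dsu(m, edges);
  double sumC = 0.0, D = 0.0;
  double bestD = 0.0;          // all-singleton baseline
  int bestLevel = 0;           // number of completed levels in the best cut
  std::vector<double> merge_sim;
  std::vector<int> merge_e1, merge_e2, merge_level;
  size_t idx = 0;
  int level = 0;
  while (idx < pairs.size()) {
    double s = pairs[idx].sim;
    ++level;
    while (idx < pairs.size() && pairs[idx].sim == s) {
      double delta;
      if (dsu.unite(pairs[idx].e1, pairs[idx].e2, delta)) {
        sumC += delta;
        merge_sim.push_back(s);
        merge_e1.push_back(pairs[idx].e1 + 1);
        merge_e2.push_back(pairs[idx].e2 + 1);
        merge_level.push_back(level);
      }
      ++idx;
    }
    D = 2.0 * sumC / m;
    if (D >= bestD - 1e-12) { bestD = D; bestLevel = level; }
  }

  // Pass 2: replay merges up to the chosen level.
  DSU dsu2(m, edges);
  double delta;
  for (size_t t = 0; t < merge_sim.size(); ++t) {
    if (merge_level[t] > bestLevel) break;
    dsu2.unite(merge_e1[t] - 1, merge_e2[t] - 1, delta);
  }
  IntegerVector labels(m);
  std::vector<int> relabel(m, 0);
  int next = 0;
  for (int e = 0; e < m; ++e) {
    int r = dsu2.find(e);
    if (relabel[r] == 0) relabel[r] = ++next;
    labels[e] = relabel[r];
  }

  return List::create(
      _["labels"] = labels,
      _["partition_density"] = bestD,
      _["n_communities"] = next,
      _["merges"] = DataFrame::create(_["sim"] = merge_sim, _["e1"] = merge_e1,
                                      _["e2"] = merge_e2, _["level"] = merge_level));
}
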