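// Girvan-Newman community decomposition for correlation networks.
//
// Edge betweenness by Brandes' accumulation (unweighted shortest paths),
// iterative removal of the maximum-betweenness edge with deterministic
// lexicographic tie-breaking (edges are supplied sorted by (i, j)), and a
// Newman-Girvan modularity trace Q = sum_k (e_kk - a_k^2) evaluated on the
// original graph for the component partition after each removal.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<std::vector<std::pair<int, int> > > AdjList; // (nbr, edge)

// Brandes edge betweenness over active edges; each unordered pair of
// endpoints contributes once (the s-loop double-counts, halved at the end).
static std::vector<double> edge_betweenness(int n,
                                            const AdjList &adj,
                                            const std::vector<char> &active,
                                            int m) {
  std::vector<double> bc(m, 0.0);
  std::vector<int> dist(n), sigma(n), order;
  std::vector<double> delta(n);
  std::vector<std::vector<std::pair<int, int> > > preds(n); // (pred, edge)
  order.reserve(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int v = 0; v < n; ++v) preds[v].clear();
    order.clear();

    std::queue<int> q;
    dist[s] = 0; sigma[s] = 1; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order.push_back(v);
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int e = adj[v][k].second;
        if (!active[e]) continue;
        int w = adj[v][k].first;
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          preds[w].push_back(std::make_pair(v, e));
        }
      }
    }
    for (int idx = (int)order.size() - 1; idx >= 0; --idx) {
      int w = order[idx];
      for (size_t k = 0; k < preds[w].size(); ++k) {
        int v = preds[w][k].first, e = preds[w][k].second;
        double c = (double)sigma[v] / (double)sigma[w] * (1.0 + delta[w]);
        bc[e] += c;
        delta[v] += c;
      }
    }
  }
  for (int e = 0; e < m; ++e) bc[e] *= 0.5;
  return bc;
}

static std::vector<int> components(int n, const AdjList &adj,
                                   const std::vector<char> &active) {
  std::vector<int> comp(n, -1);
  int c = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    std::queue<int> q; q.push(s); comp[s] = c;
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (size_t k = 0; k < adj[v].size(); ++k) {
        if (!active[adj[v][k].second]) continue;
        int w = adj[v][k].first;
        if (comp[w] < 0) { comp[w] = c; q.push(w); }
      }
    }
    ++c;
  }
  return comp;
}

// Newman-Girvan Q of a partition, measured on the original edge set.
static double modularity_q(const std::vector<int> &comp,
                           const IntegerVector &ei, const IntegerVector &ej) {
  int m = ei.size();
  if (m == 0) return 0.0; // degenerate contract: edgeless graph has Q = 0
  int nc = 0;
  for (size_t v = 0; v < comp.size(); ++v) nc = std::max(nc, comp[v] + 1);
  std::vector<double> within(nc, 0.0), degsum(nc, 0.0);
  for (int e = 0; e < m; ++e) {
    int u = ei[e] - 1, v = ej[e] - 1;
    if (comp[u] == comp[v]) within[comp[u]] += 1.0;
    degsum[comp[u]] += 1.0;
    degsum[comp[v]] += 1.0;
  }
  double Q = 0.0;
  for (int k = 0; k < nc; ++k) {
    double ekk = within[k] / m;
    double ak = degsum[k] / (2.0 * m);
    Q += ekk - ak * ak;
  }
  return Q;
}

// [[Rcpp::export(name = ".edgeBetweennessCpp")]]
NumericVector edgeBetweennessCpp(int n, IntegerVector ei, IntegerVector ej) {
  int m = ei.size();
  AdjList adj(n);
  for (int e = 0; e < m; ++e) {
    adj[ei[e] - 1].push_back(std::make_pair(ej[e] - 1, e));
    adj[ej[e] - 1].push_back(std::make_pair(ei[e] - 1, e));
  }
  std::vector<char> active(m, 1);
  std::vector<double> bc = edge_betweenness(n, adj, active, m);
  return NumericVector(bc.begin(), bc.end());
}

// Full Girvan-Newman dismantling. Edges must arrive sorted lexicographically
// by (i, j); ties in betweenness resolve to the lowest edge index, so the
// trace is fully deterministic. Returns the partition maximizing Q (earliest
// step on ties), the Q trace, and the removal order.
// [[Rcpp::export(name = ".girvanNewmanCpp")]]
List girvanNewmanCpp(int n, IntegerVector ei, IntegerVector ej) {
  int m = ei.size();
  AdjList adj(n);
  for (int e = 0; e < m; ++e) {
    adj[ei[e] - 1].push_back(std::make_pair(ej[e] - 1, e));
    adj[ej[e] - 1].push_back(std::make_pair(ei[e] - 1, e));
  }
  std::vector<char> active(m, 1);

  std::vector<int> comp = components(n, adj, active);
  double Q = modularity_q(comp, ei, ej);
  std::vector<int> bestComp = comp;
  double bestQ = Q;

  std::vector<double> traceQ; traceQ.push_back(Q);
  std::vector<int> removed; removed.reserve(m);
  std::vector<double> removedBc; removedBc.reserve(m);

  for (int step = 0; step < m; ++step) {
    std::vector<double> bc = edge_betweenness(n, adj, active, m);
    int pick = -1; double best = -1.0;
    for (int e = 0; e < m; ++e) {
      if (!active[e]) continue;
      if (bc[e] > best + 1e-9) { best = bc[e]; pick = e; }
    }
    if (pick < 0) break;
    active[pick] = 0;
    removed.push_back(pick + 1);
    removedBc.push_back(bc[pick]);
    comp = components(n, adj, active);
    Q = modularity_q(comp, ei, ej);
    traceQ.push_back(Q);
    if (Q > bestQ + 1e-12) { bestQ = Q; bestComp = comp; }
  }

  IntegerVector membership(n);
  for (int v = 0; v < n; ++v) membership[v] = bestComp[v] + 1;
  return List::create(_["membership"] = membership,
                      _["Q"] = bestQ,
                      _["traceQ"] = NumericVector(traceQ.begin(), traceQ.end()),
                      _["removed"] = IntegerVector(removed.begin(), removed.end()),
                      _["removedBetweenness"] =
                        NumericVector(removedBc.begin(), removedBc.end()));
}
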