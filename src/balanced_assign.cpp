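#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>

// Exact capacity-constrained assignment (transportation problem) by
// min-cost max-flow with successive shortest augmenting paths (SPFA).
// Points have unit supply; cluster j has capacity cap[j]; edge cost is
// cost(i, j). Graph is tiny (n + k + 2 nodes), each augmenting path
// carries one unit, so exactly n augmentations.

namespace {

struct Edge {
  int to;
  int cap;
  double cost;
  int flow;
};

struct Graph {
  std::vector<Edge> edges;
  std::vector<std::vector<int> > adj;
  explicit Graph(int n) : adj(n) {}
  void add_edge(int from, int to, int cap, double cost) {
    adj[from].push_back((int)edges.size());
    edges.push_back(Edge{to, cap, cost, 0});
    adj[to].push_back((int)edges.size());
    edges.push_back(Edge{from, 0, -cost, 0});
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector balanced_assignment_cpp(Rcpp::NumericMatrix cost,
                                            Rcpp::IntegerVector capacity) {
  const int n = cost.nrow();
  const int k = cost.ncol();
  if (capacity.size() != k)
    Rcpp::stop("capacity must have one entry per cluster");
  long total_cap = 0;
  for (int j = 0; j < k; ++j) total_cap += capacity[j];
  if (total_cap < n)
    Rcpp::stop("total capacity smaller than number of points");

  const int source = 0;
  const int sink = n + k + 1;
  Graph g(n + k + 2);
  for (int i = 0; i < n; ++i) g.add_edge(source, 1 + i, 1, 0.0);
  // point -> cluster edges in row-major order so ties resolve by point
  // index, then cluster index (deterministic)
  std::vector<int> pc_edge(n * k);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      pc_edge[i * k + j] = (int)g.edges.size();
      g.add_edge(1 + i, 1 + n + j, 1, cost(i, j));
    }
  }
  for (int j = 0; j < k; ++j) g.add_edge(1 + n + j, sink, capacity[j], 0.0);

  const double inf = std::numeric_limits<double>::infinity();
  const int nv = n + k + 2;
  std::vector<double> dist(nv);
  std::vector<int> prev_edge(nv);
  std::vector<char> in_queue(nv);

  for (int it = 0; it < n; ++it) {
    std::fill(dist.begin(), dist.end(), inf);
    std::fill(prev_edge.begin(), prev_edge.end(), -1);
    std::fill(in_queue.begin(), in_queue.end(), 0);
    dist[source] = 0.0;
    std::deque<int> q;
    q.push_back(source);
    in_queue[source] = 1;
    while (!q.empty()) {
      int u = q.front();
      q.pop_front();
      in_queue[u] = 0;
      for (size_t a = 0; a < g.adj[u].size(); ++a) {
        int eid = g.adj[u][a];
        const Edge &e = g.edges[eid];
        if (e.cap - e.flow <= 0) continue;
        double nd = dist[u] + e.cost;
        if (nd < dist[e.to] - 1e-12) {
          dist[e.to] = nd;
          prev_edge[e.to] = eid;
          if (!in_queue[e.to]) {
            q.push_back(e.to);
            in_queue[e.to] = 1;
          }
        }
      }
    }
    if (!std::isfinite(dist[sink]))
      Rcpp::stop("no augmenting path: infeasible assignment");
    for (int v = sink; v != source;) {
      int eid = prev_edge[v];
      g.edges[eid].flow += 1;
      g.edges[eid ^ 1].flow -= 1;
      v = g.edges[eid ^ 1].to;
    }
  }

  Rcpp::IntegerVector assign(n);
  for (int i = 0; i < n; ++i) {
    int lab = NA_INTEGER;
    for (int j = 0; j < k; ++j) {
      if (g.edges[pc_edge[i * k + j]].flow > 0) {
        lab = j + 1;
        break;
      }
    }
    assign[i] = lab;
  }
  return assign;
}
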