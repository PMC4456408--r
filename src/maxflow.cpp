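// Minimum-weight closed set via s-t max-flow (Dinic's algorithm).
//
// Standard transformation: source -> negative-weight nodes (capacity
// -w), positive-weight nodes -> sink (capacity w), closure arcs with
// effectively unbounded capacity.  After the max-flow, the set of
// nodes reachable from the source in the residual network is the
// unique minimal minimum-weight closed set.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

namespace {

struct Dinic {
  struct Arc { int to; double cap; int next; };
  std::vector<Arc> arcs;
  std::vector<int> head, level, it;
  int n;

  explicit Dinic(int n_) : head(n_, -1), level(n_), it(n_), n(n_) {}

  void add_arc(int u, int v, double cap) {
    arcs.push_back({v, cap, head[u]}); head[u] = (int)arcs.size() - 1;
    arcs.push_back({u, 0.0, head[v]}); head[v] = (int)arcs.size() - 1;
  }

  bool bfs(int s, int t, double eps) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int a = head[u]; a != -1; a = arcs[a].next) {
        if (arcs[a].cap > eps && level[arcs[a].to] < 0) {
          level[arcs[a].to] = level[u] + 1;
          q.push(arcs[a].to);
        }
      }
    }
    return level[t] >= 0;
  }

  double dfs(int u, int t, double f, double eps) {
    if (u == t) return f;
    for (int &a = it[u]; a != -1; a = arcs[a].next) {
      int v = arcs[a].to;
      if (arcs[a].cap > eps && level[v] == level[u] + 1) {
        double d = dfs(v, t, std::min(f, arcs[a].cap), eps);
        if (d > eps) {
          arcs[a].cap -= d;
          arcs[a ^ 1].cap += d;
          return d;
        }
      }
    }
    return 0.0;
  }

  void run(int s, int t, double eps) {
    while (bfs(s, t, eps)) {
      for (int i = 0; i < n; ++i) it[i] = head[i];
      while (dfs(s, t, R_PosInf, eps) > eps) {}
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".min_closed_set_cpp")]]
IntegerVector min_closed_set_cpp(NumericVector w, IntegerMatrix edges) {
  const int n = w.size();
  if (n == 0) return IntegerVector(0);
  const int s = n, t = n + 1;
  double big = 1.0;
  for (int i = 0; i < n; ++i) big += std::fabs(w[i]);
  const double eps = 1e-11 * big;

  Dinic d(n + 2);
  for (int i = 0; i < n; ++i) {
    if (w[i] < 0) d.add_arc(s, i, -w[i]);
    else if (w[i] > 0) d.add_arc(i, t, w[i]);
  }
  for (int e = 0; e < edges.nrow(); ++e)
    d.add_arc(edges(e, 0) - 1, edges(e, 1) - 1, big);

  d.run(s, t, eps);

  // minimal minimum closed set: residual reachability from the source
  std::vector<char> seen(n + 2, 0);
  std::queue<int> q;
  seen[s] = 1; q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int a = d.head[u]; a != -1; a = d.arcs[a].next) {
      int v = d.arcs[a].to;
      if (d.arcs[a].cap > eps && !seen[v]) { seen[v] = 1; q.push(v); }
    }
  }
  std::vector<int> out;
  for (int i = 0; i < n; ++i) if (seen[i]) out.push_back(i + 1);
  return wrap(out);
}
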