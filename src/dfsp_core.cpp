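#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <utility>
#include <cmath>

using namespace Rcpp;

// Exact brute-force k-NN over an n x 3 coordinate matrix.
// Ties in distance are broken by the lower point index; no self-loops.
// Returns 1-based neighbor indices sorted ascending by distance.
// [[Rcpp::export]]
List cpp_knn(const NumericMatrix& pts, int k) {
  const int n = pts.nrow();
  if (k >= n) k = n - 1;
  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  std::vector<double> d(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      d[j] = dx * dx + dy * dy + dz * dz;
    }
    int m = 0;
    for (int j = 0; j < n; ++j) if (j != i) ord[m++] = j;
    auto cmp = [&](int a, int b) {
      if (d[a] != d[b]) return d[a] < d[b];
      return a < b;
    };
    std::partial_sort(ord.begin(), ord.begin() + k, ord.begin() + m, cmp);
    for (int j = 0; j < k; ++j) {
      idx(i, j) = ord[j] + 1;
      dst(i, j) = std::sqrt(d[ord[j]]);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// k-NN lists for a subset of query points (1-based indices into pts).
// The query point itself is included as its own first neighbor.
// [[Rcpp::export]]
IntegerMatrix cpp_knn_query(const NumericMatrix& pts, const IntegerVector& queries,
                            int k) {
  const int n = pts.nrow(), q = queries.size();
  if (k > n) k = n;
  IntegerMatrix idx(q, k);
  std::vector<double> d(n);
  std::vector<int> ord(n);
  for (int qi = 0; qi < q; ++qi) {
    const int i = queries[qi] - 1;
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      d[j] = dx * dx + dy * dy + dz * dz;
      ord[j] = j;
    }
    auto cmp = [&](int a, int b) {
      if (d[a] != d[b]) return d[a] < d[b];
      return a < b;
    };
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(), cmp);
    for (int j = 0; j < k; ++j) idx(qi, j) = ord[j] + 1;
  }
  return idx;
}

// Greedy farthest point sampling: start at seed (1-based), repeatedly add the
// point maximizing its minimum distance to the selected set; distance ties
// broken by the lower index. Returns 1-based selected indices in pick order.
// [[Rcpp::export]]
IntegerVector cpp_fps(const NumericMatrix& pts, int m, int seed) {
  const int n = pts.nrow();
  IntegerVector out(m);
  std::vector<double> mind(n, R_PosInf);
  int cur = seed - 1;
  out[0] = seed;
  for (int s = 1; s < m; ++s) {
    const double xc = pts(cur, 0), yc = pts(cur, 1), zc = pts(cur, 2);
    int best = -1;
    double bestd = -1.0;
    for (int j = 0; j < n; ++j) {
      const double dx = pts(j, 0) - xc, dy = pts(j, 1) - yc, dz = pts(j, 2) - zc;
      const double dj = dx * dx + dy * dy + dz * dz;
      if (dj < mind[j]) mind[j] = dj;
      if (mind[j] > bestd) { bestd = mind[j]; best = j; }
    }
    cur = best;
    out[s] = best + 1;
    mind[best] = -1.0;  // never re-selected
  }
  return out;
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
};

// Persistence sweep (Quickshift++ Algorithm 1 on an arbitrary scalar field).
// Points are processed in decreasing field order (ties by lower index); a
// union-find tracks connected components of the processed subgraph of the
// symmetrized k-NN graph. A component with peak value v is a cluster core
// iff it is absorbed (by a component with a higher peak, at merge level
// lambda) only after the sweep level has dropped below (1-beta)*v, i.e.
// v*(1-beta) > lambda, or never absorbed at all. Core membership is the
// connected component of the upper level set {f > (1-beta)*v} containing
// the peak, captured as a snapshot at the moment the sweep level crosses
// that threshold. Cores below min_core_size are dropped (their points stay
// unassigned for the hill-climbing stage).
// [[Rcpp::export]]
List cpp_find_cores(const NumericVector& f, const IntegerMatrix& nn,
                    double beta, int min_core_size) {
  const int n = f.size();
  const int k = nn.ncol();

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (f[a] != f[b]) return f[a] > f[b];
    return a < b;
  });

  // symmetrized adjacency (union of directed k-NN relations), with duplicates
  std::vector<int> deg(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) { ++deg[i]; ++deg[nn(i, j) - 1]; }
  std::vector<int> off(n + 1, 0);
  for (int i = 0; i < n; ++i) off[i + 1] = off[i] + deg[i];
  std::vector<int> adj(off[n]);
  std::vector<int> fill(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) {
      const int t = nn(i, j) - 1;
      adj[off[i] + fill[i]++] = t;
      adj[off[t] + fill[t]++] = i;
    }

  UnionFind uf(n);
  std::vector<char> done(n, 0);
  std::vector<int> peak(n), head(n), tail(n), nxt(n, -1);
  std::vector<std::vector<int>> snap(n);  // per-root threshold snapshot
  std::vector<char> has_snap(n, 0), is_core(n, 0);
  // pending threshold crossings: (threshold, root), largest threshold first
  std::priority_queue<std::pair<double, int>> pending;

  auto take_snapshot = [&](int root) {
    const double thr = (1.0 - beta) * f[peak[root]];
    std::vector<int>& m = snap[root];
    for (int p = head[root]; p != -1; p = nxt[p])
      if (f[p] > thr) m.push_back(p);
    has_snap[root] = 1;
  };

  for (int oi = 0; oi < n; ++oi) {
    const int i = order[oi];
    const double lambda = f[i];
    // snapshot every live component whose threshold the level now crosses
    while (!pending.empty() && pending.top().first >= lambda) {
      const int r = pending.top().second;
      pending.pop();
      if (uf.find(r) == r && !has_snap[r]) take_snapshot(r);
    }
    done[i] = 1;
    peak[i] = i; head[i] = i; tail[i] = i; nxt[i] = -1;
    pending.push({(1.0 - beta) * f[i], i});
    for (int e = off[i]; e < off[i + 1]; ++e) {
      const int j = adj[e];
      if (!done[j]) continue;
      int ri = uf.find(i), rj = uf.find(j);
      if (ri == rj) continue;
      // winner keeps the globally higher peak (ties by lower peak index)
      int win = ri, lose = rj;
      if (f[peak[rj]] > f[peak[ri]] ||
          (f[peak[rj]] == f[peak[ri]] && peak[rj] < peak[ri])) {
        win = rj; lose = ri;
      }
      const double v = f[peak[lose]];
      if (v * (1.0 - beta) > lambda) {
        is_core[lose] = 1;            // persistent: its snapshot is a core
      } else {
        snap[lose].clear();           // absorbed too early: not a mode
        has_snap[lose] = 0;
      }
      uf.parent[lose] = win;
      nxt[tail[win]] = head[lose];
      tail[win] = tail[lose];
    }
  }

  for (int i = 0; i < n; ++i)
    if (uf.find(i) == i) {            // surviving root: always a core
      if (!has_snap[i]) take_snapshot(i);
      is_core[i] = 1;
    }

  std::vector<List> cores;
  for (int i = 0; i < n; ++i) {
    if (!is_core[i] || (int)snap[i].size() < min_core_size) continue;
    std::sort(snap[i].begin(), snap[i].end());
    IntegerVector mv(snap[i].size());
    for (size_t t = 0; t < snap[i].size(); ++t) mv[t] = snap[i][t] + 1;
    cores.push_back(List::create(_["members"] = mv,
                                 _["peak_index"] = peak[i] + 1));
  }
  return wrap(cores);
}

// Quickshift++ Algorithm 2: hill-climbing assignment. Each non-core point
// links to the nearest neighbor in its own (directed, distance-ascending)
// k-NN list with strictly greater field value; chains are followed to a core
// member or a local argmax. A terminus outside every core adopts the core of
// its nearest core member (Euclidean over all core points).
// core_id: per-point 1-based core id, 0 for points in no core.
// [[Rcpp::export]]
IntegerVector cpp_hill_climb(const NumericMatrix& pts, const NumericVector& f,
                             const IntegerMatrix& nn, const IntegerVector& core_id) {
  const int n = f.size(), k = nn.ncol();
  IntegerVector out(n);
  std::vector<int> parent(n, -1);
  std::vector<int> core_pts;
  for (int i = 0; i < n; ++i) {
    out[i] = core_id[i];
    if (core_id[i] > 0) core_pts.push_back(i);
    for (int j = 0; j < k; ++j) {
      const int t = nn(i, j) - 1;
      if (f[t] > f[i]) { parent[i] = t; break; }
    }
  }
  auto nearest_core = [&](int i) {
    int best = -1; double bestd = R_PosInf;
    for (int c : core_pts) {
      const double dx = pts(c, 0) - pts(i, 0), dy = pts(c, 1) - pts(i, 1),
                   dz = pts(c, 2) - pts(i, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < bestd) { bestd = d; best = c; }
    }
    return out[best];
  };
  std::vector<int> chain;
  for (int i = 0; i < n; ++i) {
    if (out[i] > 0) continue;
    chain.clear();
    int cur = i;
    while (out[cur] == 0 && parent[cur] != -1) {
      chain.push_back(cur);
      cur = parent[cur];
    }
    int id = out[cur];
    if (id == 0) {           // terminus is a local argmax outside every core
      chain.push_back(cur);
      id = nearest_core(cur);
    }
    for (int p : chain) out[p] = id;
  }
  return out;
}
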