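// (6,6) body-bar pebble game (Tay/Whiteley molecular framework).
//
// Each body carries 6 pebbles (degrees of freedom). A bar between bodies u
// and v is independent iff 7 pebbles can be gathered on {u, v} before it is
// placed; placing it consumes one pebble of u and records a directed edge
// u -> v. Rigid clusters are found by gathering 6 pebbles on a seed body,
// pinning them, and collecting every body that can no longer reach a free
// pebble (the failed virtual-7th-pebble test).
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct PebbleGame {
  int n;
  std::vector<int> peb;                // free pebbles per body
  std::vector<std::vector<int> > adj;  // directed placed bars (multi-edges)

  explicit PebbleGame(int n_) : n(n_), peb(n_, 6), adj(n_) {}

  void remove_edge(int p, int c) {
    std::vector<int>& v = adj[p];
    for (size_t k = 0; k < v.size(); ++k) {
      if (v[k] == c) { v[k] = v.back(); v.pop_back(); return; }
    }
  }

  // Depth-first search from u for a body holding a free pebble; bodies with
  // block[] set cannot donate pebbles (traversal through them is allowed).
  // On success one pebble is moved to u by reversing the search path.
  bool find_pebble(int u, const std::vector<char>& block) {
    std::vector<int> parent(n, -2), stack;
    parent[u] = -1;
    stack.push_back(u);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (parent[w] != -2) continue;
        parent[w] = v;
        if (peb[w] > 0 && !block[w]) {
          peb[w]--; peb[u]++;
          int c = w, p = parent[w];
          while (p != -1) {
            remove_edge(p, c);
            adj[c].push_back(p);
            c = p; p = parent[c];
          }
          return true;
        }
        stack.push_back(w);
      }
    }
    return false;
  }

  // Gather pebbles for bar (u, v): true iff 7 pebbles can sit on {u, v}.
  bool gather_seven(int u, int v) {
    std::vector<char> block(n, 0);
    while (peb[u] + peb[v] < 7) {
      block[v] = 1; block[u] = 0;
      bool got = find_pebble(u, block);
      if (!got) {
        block[u] = 1; block[v] = 0;
        got = find_pebble(v, block);
      }
      if (!got) return false;
    }
    return true;
  }

  // Insert one bar; returns true if independent.
  bool insert_bar(int u, int v) {
    if (!gather_seven(u, v)) return false;
    // peb[u] >= 1 here because peb[v] <= 6 and the pair holds >= 7
    peb[u]--;
    adj[u].push_back(v);
    return true;
  }

  void collect_six(int u) {
    std::vector<char> block(n, 0);
    while (peb[u] < 6) {
      if (!find_pebble(u, block)) break;  // cannot happen in a valid game
    }
  }

  // Bodies that can reach a free pebble not pinned on u, via directed paths.
  std::vector<char> can_reach_free(int u) {
    std::vector<std::vector<int> > radj(n);
    for (int v = 0; v < n; ++v)
      for (size_t k = 0; k < adj[v].size(); ++k)
        radj[adj[v][k]].push_back(v);
    std::vector<char> ok(n, 0);
    std::vector<int> stack;
    for (int v = 0; v < n; ++v) {
      if (v != u && peb[v] > 0) { ok[v] = 1; stack.push_back(v); }
    }
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      for (size_t k = 0; k < radj[v].size(); ++k) {
        int w = radj[v][k];
        if (!ok[w]) { ok[w] = 1; stack.push_back(w); }
      }
    }
    return ok;
  }
};

// connected components of the undirected bar multigraph
std::vector<int> components(int n, const IntegerVector& ei,
                            const IntegerVector& ej) {
  std::vector<std::vector<int> > g(n);
  for (int k = 0; k < ei.size(); ++k) {
    g[ei[k] - 1].push_back(ej[k] - 1);
    g[ej[k] - 1].push_back(ei[k] - 1);
  }
  std::vector<int> comp(n, -1);
  int c = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (comp[s] != -1) continue;
    comp[s] = c; stack.push_back(s);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      for (size_t k = 0; k < g[v].size(); ++k)
        if (comp[g[v][k]] == -1) { comp[g[v][k]] = c; stack.push_back(g[v][k]); }
    }
    ++c;
  }
  return comp;
}

}  // namespace

// [[Rcpp::export(name = ".pebble_decompose")]]
List pebble_decompose_cpp(int n_bodies, IntegerVector bar_i, IntegerVector bar_j,
                          IntegerVector bar_mult) {
  if (n_bodies < 1) stop("network must have at least one body");
  PebbleGame pg(n_bodies);
  int independent = 0, redundant = 0;
  IntegerVector bar_indep(bar_i.size());
  for (int k = 0; k < bar_i.size(); ++k) {
    int u = bar_i[k] - 1, v = bar_j[k] - 1, m = bar_mult[k];
    if (u < 0 || u >= n_bodies || v < 0 || v >= n_bodies)
      stop("bar endpoint outside body range");
    if (u == v) stop("self-edges are not allowed");
    int indep_here = 0;
    for (int r = 0; r < m; ++r) {
      if (pg.insert_bar(u, v)) { ++independent; ++indep_here; }
      else ++redundant;
    }
    bar_indep[k] = indep_here;
  }

  // rigid-cluster decomposition
  IntegerVector cluster(n_bodies, NA_INTEGER);
  int cid = 0;
  for (int u = 0; u < n_bodies; ++u) {
    if (cluster[u] != NA_INTEGER) continue;
    ++cid;
    cluster[u] = cid;
    pg.collect_six(u);
    std::vector<char> ok = pg.can_reach_free(u);
    for (int v = u + 1; v < n_bodies; ++v) {
      if (cluster[v] == NA_INTEGER && !ok[v]) cluster[v] = cid;
    }
  }

  // per-component floppy modes: free pebbles in component minus the 6
  // global rigid-body motions
  std::vector<int> comp = components(n_bodies, bar_i, bar_j);
  int ncomp = 0;
  for (int v = 0; v < n_bodies; ++v) if (comp[v] + 1 > ncomp) ncomp = comp[v] + 1;
  IntegerVector comp_free(ncomp), comp_size(ncomp), comp_id(n_bodies);
  for (int v = 0; v < n_bodies; ++v) {
    comp_free[comp[v]] += pg.peb[v];
    comp_size[comp[v]] += 1;
    comp_id[v] = comp[v] + 1;
  }
  IntegerVector comp_floppy(ncomp);
  int floppy_total = 0;
  for (int c = 0; c < ncomp; ++c) {
    comp_floppy[c] = comp_free[c] - 6;
    floppy_total += comp_floppy[c];
  }

  return List::create(
      _["cluster"] = cluster,
      _["independent_bars"] = independent,
      _["redundant_bars"] = redundant,
      _["bar_independent"] = bar_indep,
      _["component"] = comp_id,
      _["component_size"] = comp_size,
      _["component_floppy"] = comp_floppy,
      _["floppy_modes_internal"] = floppy_total);
}

// Decompose many networks sharing one body count; bars_list holds one
// 3-column integer matrix (i, j, mult) per network. Returns, per network,
// the member mask of the largest rigid cluster (ties toward the cluster
// holding the smallest body index) as a logical matrix bodies x networks.
// [[Rcpp::export(name = ".pebble_largest_member_many")]]
LogicalMatrix pebble_largest_member_many(int n_bodies, List bars_list) {
  int m = bars_list.size();
  LogicalMatrix out(n_bodies, m);
  for (int s = 0; s < m; ++s) {
    IntegerMatrix b = bars_list[s];
    IntegerVector bi = b(_, 0), bj = b(_, 1), bm = b(_, 2);
    List res = pebble_decompose_cpp(n_bodies, bi, bj, bm);
    IntegerVector cl = res["cluster"];
    int ncl = 0;
    for (int v = 0; v < n_bodies; ++v) if (cl[v] > ncl) ncl = cl[v];
    std::vector<int> size(ncl + 1, 0);
    for (int v = 0; v < n_bodies; ++v) size[cl[v]]++;
    int best = 1;
    for (int c = 2; c <= ncl; ++c) if (size[c] > size[best]) best = c;
    // clusters are numbered by first (smallest) body index, so the first
    // cluster attaining the maximal size already wins ties correctly
    for (int v = 0; v < n_bodies; ++v) out(v, s) = (cl[v] == best);
  }
  return out;
}
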