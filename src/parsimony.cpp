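// Parsimony scoring and tree search for binary presence/absence characters.
//
// Wagner parsimony scores a character by the minimum number of state
// changes (gains and losses equally weighted, no assumed ancestral state);
// computed by Sankoff dynamic programming with unit costs, which is exact
// on binary and multifurcating trees and independent of root placement.
//
// Camin-Sokal parsimony forbids losses: presence is derived, so the set of
// present nodes must be a union of rooted subtrees.  The tree is rooted at
// a designated all-absent ancestor leaf and the score of a character is
// the number of maximal subtrees whose leaves all carry it (one gain per
// maximal carrier subtree).
//
// Search strategies: exhaustive enumeration / branch-and-bound by stepwise
// insertion of taxa into every edge (the partial-tree score is a lower
// bound on any completion, so pruning is exact and ties survive), and a
// heuristic of seeded jumbled stepwise addition followed by
// nearest-neighbour-interchange refinement.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
#include <map>
#include <random>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

typedef std::vector<std::array<int, 2> > EdgeVec;

static const double BIG = 1e18;

// Generic scorer.  Nodes are arbitrary non-negative ids; taxa are ids
// < n_taxa with rows in `states`.  method 0 = Wagner, 1 = Camin-Sokal
// (rooted at leaf `root`; for Wagner `root` may be -1).
static double score_tree(const EdgeVec& edges, const IntegerMatrix& states,
                         const NumericVector& w, int method, int root,
                         double stop_above = BIG) {
  int n_taxa = states.nrow();
  int maxid = 0;
  for (size_t i = 0; i < edges.size(); ++i)
    maxid = std::max(maxid, std::max(edges[i][0], edges[i][1]));
  int m = maxid + 1;
  std::vector<std::vector<int> > adj(m);
  for (size_t i = 0; i < edges.size(); ++i) {
    adj[edges[i][0]].push_back(edges[i][1]);
    adj[edges[i][1]].push_back(edges[i][0]);
  }
  if (root < 0) root = edges[0][0];
  // iterative DFS -> postorder node list with parents
  std::vector<int> order, parent(m, -2), stack;
  order.reserve(m);
  stack.push_back(root);
  parent[root] = -1;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    for (size_t j = 0; j < adj[v].size(); ++j) {
      int u = adj[v][j];
      if (u != parent[v]) { parent[u] = v; stack.push_back(u); }
    }
  }
  std::reverse(order.begin(), order.end()); // children before parents

  int n_char = states.ncol();
  double total = 0.0;
  std::vector<double> c0(m), c1(m);
  std::vector<char> pure(m);
  for (int ch = 0; ch < n_char; ++ch) {
    if (method == 0) { // Wagner: Sankoff unit costs
      for (size_t oi = 0; oi < order.size(); ++oi) {
        int v = order[oi];
        if (v < n_taxa && adj[v].size() <= 1) { // leaf
          int s = states(v, ch);
          c0[v] = (s == 0) ? 0.0 : BIG;
          c1[v] = (s == 1) ? 0.0 : BIG;
        } else {
          double a = 0.0, b = 0.0;
          for (size_t j = 0; j < adj[v].size(); ++j) {
            int u = adj[v][j];
            if (u == parent[v]) continue;
            a += std::min(c0[u], c1[u] + 1.0);
            b += std::min(c1[u], c0[u] + 1.0);
          }
          c0[v] = a; c1[v] = b;
        }
      }
      total += w[ch] * std::min(c0[root], c1[root]);
    } else { // Camin-Sokal: maximal carrier subtrees below the ancestor leaf
      double gains = 0.0;
      for (size_t oi = 0; oi < order.size(); ++oi) {
        int v = order[oi];
        if (v < n_taxa && adj[v].size() <= 1) {
          pure[v] = (v == root) ? 0 : (states(v, ch) == 1);
        } else {
          char p = 1;
          for (size_t j = 0; j < adj[v].size(); ++j) {
            int u = adj[v][j];
            if (u == parent[v]) continue;
            if (!pure[u]) p = 0;
          }
          pure[v] = p;
        }
      }
      for (int v = 0; v < m; ++v) {
        if (v == root || parent[v] == -2) continue;
        if (pure[v] && (parent[v] == root || !pure[parent[v]]))
          gains += 1.0;
      }
      total += w[ch] * gains;
    }
    if (total > stop_above) return total; // early exit for bounding
  }
  return total;
}

// [[Rcpp::export]]
double score_tree_cpp(IntegerMatrix edge, IntegerMatrix states,
                      NumericVector weights, int method, int root) {
  EdgeVec edges(edge.nrow());
  for (int i = 0; i < edge.nrow(); ++i) {
    edges[i][0] = edge(i, 0); edges[i][1] = edge(i, 1);
  }
  return score_tree(edges, states, weights, method, root);
}

// ---- search ---------------------------------------------------------------

struct SearchState {
  const IntegerMatrix* states;
  const NumericVector* weights;
  int method;
  int n_taxa;
  double best;
  std::vector<EdgeVec> best_trees;
  std::vector<std::string> best_keys;
  bool prune;
  long long n_scored;
};

// canonical key: sorted list of taxon bitmasks (side not containing taxon 0)
static std::string tree_key(const EdgeVec& edges, int n_taxa) {
  int maxid = 0;
  for (size_t i = 0; i < edges.size(); ++i)
    maxid = std::max(maxid, std::max(edges[i][0], edges[i][1]));
  std::vector<std::vector<int> > adj(maxid + 1);
  for (size_t i = 0; i < edges.size(); ++i) {
    adj[edges[i][0]].push_back(edges[i][1]);
    adj[edges[i][1]].push_back(edges[i][0]);
  }
  std::vector<std::uint64_t> masks;
  for (size_t i = 0; i < edges.size(); ++i) {
    // taxa on the side of edges[i][1] when the edge is cut
    std::vector<int> stack;
    std::vector<char> seen(maxid + 1, 0);
    stack.push_back(edges[i][1]);
    seen[edges[i][0]] = 1; seen[edges[i][1]] = 1;
    std::uint64_t mask = 0;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v < n_taxa && adj[v].size() <= 1) mask |= (std::uint64_t(1) << v);
      for (size_t j = 0; j < adj[v].size(); ++j)
        if (!seen[adj[v][j]]) { seen[adj[v][j]] = 1; stack.push_back(adj[v][j]); }
    }
    if (mask & 1) mask = ~mask & ((std::uint64_t(1) << n_taxa) - 1);
    masks.push_back(mask);
  }
  std::sort(masks.begin(), masks.end());
  std::string key;
  char buf[24];
  for (size_t i = 0; i < masks.size(); ++i) {
    std::snprintf(buf, sizeof(buf), "%llx.", (unsigned long long)masks[i]);
    key += buf;
  }
  return key;
}

static void consider_tree(SearchState& st, const EdgeVec& edges, double score) {
  const double eps = 1e-9;
  if (score < st.best - eps) {
    st.best = score;
    st.best_trees.clear();
    st.best_keys.clear();
  }
  if (score <= st.best + eps) {
    std::string key = tree_key(edges, st.n_taxa);
    for (size_t i = 0; i < st.best_keys.size(); ++i)
      if (st.best_keys[i] == key) return;
    st.best_keys.push_back(key);
    st.best_trees.push_back(edges);
  }
}

// DFS over stepwise insertion of order[k..] into every edge
static void dfs_add(SearchState& st, EdgeVec& edges,
                    const std::vector<int>& order, size_t k, int next_internal,
                    int root) {
  if (k == order.size()) {
    double s = score_tree(edges, *st.states, *st.weights, st.method, root);
    st.n_scored++;
    consider_tree(st, edges, s);
    return;
  }
  int taxon = order[k];
  size_t n_edges = edges.size();
  for (size_t e = 0; e < n_edges; ++e) {
    int u = edges[e][0], v = edges[e][1];
    int w = next_internal;
    edges[e][1] = w;
    edges.push_back({{w, v}});
    edges.push_back({{w, taxon}});
    bool go = true;
    if (st.prune) {
      double s = score_tree(edges, *st.states, *st.weights, st.method, root,
                            st.best + 1e-9);
      st.n_scored++;
      if (s > st.best + 1e-9) go = false;
    }
    if (go) dfs_add(st, edges, order, k + 1, next_internal + 1, root);
    edges.pop_back();
    edges.pop_back();
    edges[e][1] = v;
  }
}

// greedy stepwise addition, then NNI refinement; returns final tree
static EdgeVec greedy_build_nni(SearchState& st, const std::vector<int>& order,
                                int root) {
  EdgeVec edges;
  int N = st.n_taxa;
  int internal = N; // internal node ids start at n_taxa
  edges.push_back({{internal, order[0]}});
  edges.push_back({{internal, order[1]}});
  edges.push_back({{internal, order[2]}});
  internal++;
  for (size_t k = 3; k < order.size(); ++k) {
    int taxon = order[k];
    double best_s = BIG;
    size_t best_e = 0;
    for (size_t e = 0; e < edges.size(); ++e) {
      int v = edges[e][1];
      edges[e][1] = internal;
      edges.push_back({{internal, v}});
      edges.push_back({{internal, taxon}});
      double s = score_tree(edges, *st.states, *st.weights, st.method, root);
      st.n_scored++;
      edges.pop_back(); edges.pop_back();
      edges[e][1] = v;
      if (s < best_s - 1e-9) { best_s = s; best_e = e; }
    }
    int v = edges[best_e][1];
    edges[best_e][1] = internal;
    edges.push_back({{internal, v}});
    edges.push_back({{internal, taxon}});
    internal++;
  }
  // NNI refinement (first-improvement passes until stable)
  double cur = score_tree(edges, *st.states, *st.weights, st.method, root);
  st.n_scored++;
  bool improved = true;
  while (improved) {
    improved = false;
    for (size_t e = 0; e < edges.size() && !improved; ++e) {
      int u = edges[e][0], v = edges[e][1];
      if (u < N || v < N) continue; // need an internal edge
      // neighbours of u (other than v) and of v (other than u)
      std::vector<std::pair<size_t, int> > un, vn; // (edge index, other node)
      for (size_t f = 0; f < edges.size(); ++f) {
        if (f == e) continue;
        if (edges[f][0] == u) un.push_back(std::make_pair(f, edges[f][1]));
        else if (edges[f][1] == u) un.push_back(std::make_pair(f, edges[f][0]));
        else if (edges[f][0] == v) vn.push_back(std::make_pair(f, edges[f][1]));
        else if (edges[f][1] == v) vn.push_back(std::make_pair(f, edges[f][0]));
      }
      if (un.size() != 2 || vn.size() != 2) continue;
      for (int alt = 0; alt < 2 && !improved; ++alt) {
        // swap subtree un[1] with vn[alt]
        size_t fe1 = un[1].first, fe2 = vn[alt].first;
        EdgeVec trial = edges;
        // re-attach: edge fe1 connects u <-> vn[alt].second,
        //            edge fe2 connects v <-> un[1].second
        trial[fe1][0] = u; trial[fe1][1] = vn[alt].second;
        trial[fe2][0] = v; trial[fe2][1] = un[1].second;
        double s = score_tree(trial, *st.states, *st.weights, st.method, root);
        st.n_scored++;
        if (s < cur - 1e-9) {
          edges = trial;
          cur = s;
          improved = true;
        }
      }
    }
  }
  return edges;
}

// [[Rcpp::export]]
List pars_search_cpp(IntegerMatrix states, NumericVector weights, int method,
                     int strategy, int n_jumble, int seed) {
  int N = states.nrow();
  if (N < 3) stop("need at least 3 taxa");
  SearchState st;
  st.states = &states;
  st.weights = &weights;
  st.method = method;
  st.n_taxa = N;
  st.best = BIG;
  st.prune = (strategy == 1);
  st.n_scored = 0;
  // Camin-Sokal roots at the ancestor leaf, which the caller places at
  // taxon index 0; Wagner scoring roots anywhere.
  int root = (method == 1) ? 0 : -1;

  if (strategy == 0 || strategy == 1) {
    std::vector<int> order(N);
    for (int i = 0; i < N; ++i) order[i] = i;
    EdgeVec edges;
    edges.push_back({{N, 0}});
    edges.push_back({{N, 1}});
    edges.push_back({{N, 2}});
    dfs_add(st, edges, order, 3, N + 1, root);
  } else {
    std::mt19937 rng(static_cast<std::uint32_t>(seed));
    for (int j = 0; j < n_jumble; ++j) {
      std::vector<int> order(N);
      for (int i = 0; i < N; ++i) order[i] = i;
      int lo = (method == 1) ? 1 : 0; // keep the ancestor leaf first
      for (int i = N - 1; i > lo; --i) {
        std::uniform_int_distribution<int> d(lo, i);
        std::swap(order[i], order[d(rng)]);
      }
      EdgeVec tr = greedy_build_nni(st, order, root);
      double s = score_tree(tr, states, weights, method, root);
      st.n_scored++;
      consider_tree(st, tr, s);
    }
  }

  List trees(st.best_trees.size());
  for (size_t i = 0; i < st.best_trees.size(); ++i) {
    const EdgeVec& ev = st.best_trees[i];
    IntegerMatrix em(ev.size(), 2);
    for (size_t r = 0; r < ev.size(); ++r) {
      em(r, 0) = ev[r][0]; em(r, 1) = ev[r][1];
    }
    trees[i] = em;
  }
  return List::create(_["trees"] = trees, _["score"] = st.best,
                      _["n_scored"] = (double)st.n_scored);
}
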