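#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// Parsimony scoring by generalized Sankoff dynamic programming.
//
// Trees arrive as a 2-column integer edge matrix over arbitrary positive
// node ids plus `tipIds`, the node id of each data row (taxon).  This keeps
// tree surgery in R free of ape's renumbering conventions; conversion to
// `phylo` happens at the package surface.
//
// Characters are bitmask-encoded: bit j of statemask(taxon, char) set means
// state j is permitted at that leaf (singleton for observed cells, the full
// alphabet for missing/gap, a larger set for polymorphic cells).  Cost is
// 0/1 between states for unordered characters and |i - j| for ordered ones;
// both cost transforms run in O(k) per edge, so polytomies and multistate
// characters are exact at no structural cost.

static const int BIG = 1 << 28;

struct Tree {
  int n_nodes;                       // compact node count
  std::vector<int> post;             // postorder (compact ids), root last
  std::vector<int> parent;           // compact parent id, -1 at root
  std::vector<int> leaf_row;         // data row (0-based) or -1 if internal
  std::vector<int> edge_row_of;      // input edge row for (parent[v], v), -1 at root
};

// Map arbitrary ids to 0..m-1 and orient the tree from a root.
static Tree build_tree(const IntegerMatrix& edge, const IntegerVector& tipIds) {
  int m = edge.nrow();
  int maxid = 0;
  for (int i = 0; i < m; ++i) {
    maxid = std::max(maxid, std::max(edge(i, 0), edge(i, 1)));
  }
  for (int i = 0; i < tipIds.size(); ++i) maxid = std::max(maxid, tipIds[i]);
  std::vector<int> idmap(maxid + 1, -1);
  int n = 0;
  for (int i = 0; i < m; ++i) {
    for (int c = 0; c < 2; ++c) {
      int id = edge(i, c);
      if (idmap[id] < 0) idmap[id] = n++;
    }
  }
  Tree T;
  T.n_nodes = n;
  T.leaf_row.assign(n, -1);
  for (int i = 0; i < tipIds.size(); ++i) {
    int id = tipIds[i];
    if (id > maxid || idmap[id] < 0) stop("tip id not present in edge matrix");
    T.leaf_row[idmap[id]] = i;
  }
  // adjacency with edge rows
  std::vector<std::vector<std::pair<int,int>>> adj(n);
  for (int i = 0; i < m; ++i) {
    int a = idmap[edge(i, 0)], b = idmap[edge(i, 1)];
    adj[a].push_back({b, i});
    adj[b].push_back({a, i});
  }
  // root: prefer an internal (non-leaf) node
  int root = -1;
  for (int v = 0; v < n && root < 0; ++v)
    if (T.leaf_row[v] < 0) root = v;
  if (root < 0) root = idmap[edge(0, 0)];
  T.parent.assign(n, -1);
  T.edge_row_of.assign(n, -1);
  // iterative DFS for pre/post order
  std::vector<int> stack_, pre;
  stack_.push_back(root);
  std::vector<char> seen(n, 0);
  seen[root] = 1;
  while (!stack_.empty()) {
    int v = stack_.back(); stack_.pop_back();
    pre.push_back(v);
    for (auto& pr : adj[v]) {
      if (!seen[pr.first]) {
        seen[pr.first] = 1;
        T.parent[pr.first] = v;
        T.edge_row_of[pr.first] = pr.second;
        stack_.push_back(pr.first);
      }
    }
  }
  if ((int)pre.size() != n) stop("edge matrix is not a connected tree");
  T.post.assign(pre.rbegin(), pre.rend());
  return T;
}

// min-plus transform of a cost vector across one edge
static inline void transmit(const int* c, int* out, int k, bool ordered) {
  if (ordered) {
    int run = BIG;
    for (int i = 0; i < k; ++i) { run = std::min(run + 1, c[i]); out[i] = run; }
    run = BIG;
    for (int i = k - 1; i >= 0; --i) { run = std::min(run + 1, c[i]); out[i] = std::min(out[i], run); }
  } else {
    int mn = BIG;
    for (int i = 0; i < k; ++i) mn = std::min(mn, c[i]);
    for (int i = 0; i < k; ++i) out[i] = std::min(c[i], mn + 1);
  }
}

static inline void leaf_costs(int mask, int* c, int k) {
  for (int i = 0; i < k; ++i) c[i] = (mask >> i) & 1 ? 0 : BIG;
}

// Down-pass (subtree) costs for one character; returns min root cost.
// D is a flat n_nodes x k buffer.
static int down_pass(const Tree& T, const IntegerMatrix& statemask, int ch,
                     int k, bool ordered, std::vector<int>& D) {
  int n = T.n_nodes;
  std::vector<int> tr(k);
  for (int idx = 0; idx < n; ++idx) {
    int v = T.post[idx];
    int* Dv = &D[(size_t)v * k];
    if (T.leaf_row[v] >= 0) {
      leaf_costs(statemask(T.leaf_row[v], ch), Dv, k);
    } else {
      std::fill(Dv, Dv + k, 0);
    }
  }
  for (int idx = 0; idx < n; ++idx) {
    int v = T.post[idx];
    int p = T.parent[v];
    if (p < 0) continue;
    transmit(&D[(size_t)v * k], tr.data(), k, ordered);
    int* Dp = &D[(size_t)p * k];
    for (int i = 0; i < k; ++i) Dp[i] = std::min(Dp[i] + tr[i], BIG);
  }
  int root = T.post[n - 1];
  int best = BIG;
  for (int i = 0; i < k; ++i) best = std::min(best, D[(size_t)root * k + i]);
  return best;
}

static IntegerVector score_tree(const IntegerMatrix& edge, const IntegerVector& tipIds,
                                const IntegerMatrix& statemask, const IntegerVector& nstates,
                                const LogicalVector& ordered) {
  Tree T = build_tree(edge, tipIds);
  int nc = statemask.ncol();
  IntegerVector out(nc);
  int kmax = 1;
  for (int ch = 0; ch < nc; ++ch) kmax = std::max(kmax, nstates[ch]);
  std::vector<int> D((size_t)T.n_nodes * kmax);
  for (int ch = 0; ch < nc; ++ch) {
    out[ch] = down_pass(T, statemask, ch, nstates[ch], ordered[ch], D);
    if (out[ch] >= BIG) stop("character has an empty state set at some leaf");
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector score_edges_cpp(IntegerMatrix edge, IntegerVector tipIds,
                              IntegerMatrix statemask, IntegerVector nstates,
                              LogicalVector ordered) {
  return score_tree(edge, tipIds, statemask, nstates, ordered);
}

// Count, per input edge row, the characters forced to change on that edge
// under every most-parsimonious reconstruction (the rule-1 collapse test:
// contract internal edges whose count is zero).
// [[Rcpp::export]]
IntegerVector forced_changes_cpp(IntegerMatrix edge, IntegerVector tipIds,
                                 IntegerMatrix statemask, IntegerVector nstates,
                                 LogicalVector ordered) {
  Tree T = build_tree(edge, tipIds);
  int nc = statemask.ncol();
  int n = T.n_nodes;
  IntegerVector forced(edge.nrow());
  int kmax = 1;
  for (int ch = 0; ch < nc; ++ch) kmax = std::max(kmax, nstates[ch]);
  std::vector<int> D((size_t)n * kmax), A((size_t)n * kmax), tr(kmax), rest(kmax);
  for (int ch = 0; ch < nc; ++ch) {
    int k = nstates[ch];
    bool ord = ordered[ch];
    int L = down_pass(T, statemask, ch, k, ord, D);
    // top-down: A[v][t] = min cost of the tree outside subtree(v), viewed at
    // v's end of the stem edge (edge cost included)
    int root = T.post[n - 1];
    std::fill(&A[(size_t)root * k], &A[(size_t)root * k] + k, 0);
    for (int idx = n - 1; idx >= 0; --idx) {
      int v = T.post[idx];
      int p = T.parent[v];
      if (p < 0) continue;
      // rest_pv[s] = A[p][s] + D[p][s] - transmit_v[s]  (cost outside v's
      // subtree with p's end fixed at s).  Subtracting the transmitted
      // contribution of v needs care with saturation.
      transmit(&D[(size_t)v * k], tr.data(), k, ord);
      const int* Ap = &A[(size_t)p * k];
      const int* Dp = &D[(size_t)p * k];
      for (int s = 0; s < k; ++s) {
        int val = (Dp[s] >= BIG || Ap[s] >= BIG) ? BIG : Ap[s] + Dp[s] - tr[s];
        rest[s] = std::min(val, BIG);
      }
      transmit(rest.data(), &A[(size_t)v * k], k, ord);
      // forced iff no optimal reconstruction has equal states at both ends
      const int* Dv = &D[(size_t)v * k];
      int eq = BIG;
      for (int s = 0; s < k; ++s) eq = std::min(eq, std::min(rest[s], BIG - Dv[s]) + Dv[s]);
      if (eq > L) forced[T.edge_row_of[v]]++;
    }
  }
  return forced;
}

// ---- TBR scan ------------------------------------------------------------

struct EdgeList {
  std::vector<std::array<int,2>> e;
};

static double weighted_total(const IntegerVector& steps, const NumericVector& w) {
  double s = 0;
  for (int i = 0; i < steps.size(); ++i) s += steps[i] * w[i];
  return s;
}

static IntegerMatrix to_matrix(const EdgeList& el) {
  IntegerMatrix m(el.e.size(), 2);
  for (size_t i = 0; i < el.e.size(); ++i) { m(i, 0) = el.e[i][0]; m(i, 1) = el.e[i][1]; }
  return m;
}

// Enumerate and score every tree one TBR move away (bisect each edge, then
// reconnect every edge pair across the two fragments, subdividing at the
// chosen edges).  Neighbors with weighted length <= keep_bound are returned
// as edge matrices; the caller deduplicates by bipartition hash.  The input
// topology itself is regenerated by some reconnections and is not filtered
// here.
// [[Rcpp::export]]
List tbr_scan_cpp(IntegerMatrix edge, IntegerVector tipIds,
                  IntegerMatrix statemask, IntegerVector nstates,
                  LogicalVector ordered, NumericVector weights,
                  double keep_bound) {
  int m = edge.nrow();
  int maxid = 0;
  for (int i = 0; i < m; ++i) maxid = std::max(maxid, std::max(edge(i, 0), edge(i, 1)));
  std::vector<char> is_tip(maxid + 3, 0);
  for (int i = 0; i < tipIds.size(); ++i) is_tip[tipIds[i]] = 1;

  double best = R_PosInf;
  std::vector<IntegerMatrix> kept;
  std::vector<double> kept_len;

  for (int cut = 0; cut < m; ++cut) {
    // component split by removing edge `cut`
    std::vector<std::vector<std::pair<int,int>>> adj(maxid + 1);
    for (int i = 0; i < m; ++i) {
      if (i == cut) continue;
      adj[edge(i, 0)].push_back({edge(i, 1), i});
      adj[edge(i, 1)].push_back({edge(i, 0), i});
    }
    int u = edge(cut, 0), v = edge(cut, 1);
    std::vector<signed char> comp(maxid + 1, -1);
    for (int srcside = 0; srcside < 2; ++srcside) {
      int src = srcside == 0 ? u : v;
      std::vector<int> st{src};
      comp[src] = srcside;
      while (!st.empty()) {
        int x = st.back(); st.pop_back();
        for (auto& pr : adj[x]) if (comp[pr.first] < 0) { comp[pr.first] = srcside; st.push_back(pr.first); }
      }
    }
    // suppress the cut endpoints if they become degree-2; record the merged
    // ("bridged") edge so it can still serve as a reconnection point
    std::vector<std::array<int,2>> base;
    std::array<int,2> bridged[2] = {{-1, -1}, {-1, -1}};
    std::vector<char> dropped(maxid + 1, 0);
    for (int side = 0; side < 2; ++side) {
      int x = side == 0 ? u : v;
      if (!is_tip[x] && adj[x].size() == 2) {
        bridged[side] = {adj[x][0].first, adj[x][1].first};
        dropped[x] = 1;
      }
    }
    for (int i = 0; i < m; ++i) {
      if (i == cut) continue;
      int a = edge(i, 0), b = edge(i, 1);
      if (dropped[a] || dropped[b]) continue;
      base.push_back({a, b});
    }
    for (int side = 0; side < 2; ++side)
      if (bridged[side][0] >= 0) base.push_back({bridged[side][0], bridged[side][1]});

    // reconnection points per side: every edge of that side, or the lone
    // node if the fragment is a single leaf
    std::vector<int> lone(2, -1);
    std::vector<std::vector<int>> pts(2); // indices into base
    for (size_t i = 0; i < base.size(); ++i) {
      int side = comp[base[i][0]];
      pts[side].push_back(i);
    }
    for (int side = 0; side < 2; ++side) {
      if (pts[side].empty()) {
        // fragment is a single node (a leaf, or endpoint that was a leaf)
        int x = side == 0 ? u : v;
        lone[side] = dropped[x] ? -1 : x;
        if (lone[side] < 0) continue;
      }
    }
    int na = maxid + 1, nb = maxid + 2;
    auto attach_ids = [&](int side, int choice, EdgeList& out, int newnode) -> int {
      // returns the node to connect; subdivides base edge `choice` at newnode
      if (choice < 0) return lone[side];
      auto& be = out.e;
      int a = base[choice][0], b = base[choice][1];
      for (auto& e2 : be) {
        if ((e2[0] == a && e2[1] == b) || (e2[0] == b && e2[1] == a)) {
          e2 = {a, newnode};
          be.push_back({newnode, b});
          return newnode;
        }
      }
      return -1;
    };
    std::vector<int> ch0 = pts[0].empty() ? std::vector<int>{-1} : std::vector<int>(pts[0].begin(), pts[0].end());
    std::vector<int> ch1 = pts[1].empty() ? std::vector<int>{-1} : std::vector<int>(pts[1].begin(), pts[1].end());
    for (int c0 : ch0) {
      if (c0 < 0 && lone[0] < 0) continue;
      for (int c1 : ch1) {
        if (c1 < 0 && lone[1] < 0) continue;
        EdgeList nb_el;
        nb_el.e = base;
        int x0 = attach_ids(0, c0, nb_el, na);
        int x1 = attach_ids(1, c1, nb_el, nb);
        if (x0 < 0 || x1 < 0) continue;
        nb_el.e.push_back({x0, x1});
        IntegerMatrix em = to_matrix(nb_el);
        IntegerVector steps = score_tree(em, tipIds, statemask, nstates, ordered);
        double len = weighted_total(steps, weights);
        if (len < best) best = len;
        if (len <= keep_bound) {
          kept.push_back(em);
          kept_len.push_back(len);
        }
      }
    }
  }
  return List::create(_["best"] = best,
                      _["kept"] = wrap(kept),
                      _["kept_len"] = wrap(kept_len));
}
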