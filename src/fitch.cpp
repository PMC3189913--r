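#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Fitch small-parsimony scoring on binary trees, batched over topologies.
//
// Node ids: tips are 1..nTips (a tree may use a subset of them); internal
// nodes are any ids > nTips. Edges are undirected pairs; each tree is rooted
// at its smallest tip for the downpass, so every internal node has exactly
// two children (binary unrooted topologies only).
//
// States are bitmasks over up to 31 states; a missing entry ('?') must be
// encoded upstream as the union of the character's observed states.

static inline int popcount_steps(int a, int b, int &state) {
  int inter = a & b;
  if (inter) { state = inter; return 0; }
  state = a | b;
  return 1;
}

// Core: per-character Fitch steps for one tree.
// edges: 2*nEdge ints (p,c,p,c,...); tipStates: nTipsTotal x nChar bitmasks.
static void fitch_one(const int *edges, int nEdge, const IntegerMatrix &tipStates,
                      int nTips, std::vector<int> &steps_out,
                      std::vector<int> &deg, std::vector<int> &off,
                      std::vector<int> &adj, std::vector<int> &par,
                      std::vector<int> &post, std::vector<int> &st) {
  int nChar = tipStates.ncol();
  int maxNode = 0;
  for (int i = 0; i < 2 * nEdge; ++i) maxNode = std::max(maxNode, edges[i]);
  if ((int)deg.size() < maxNode + 2) {
    deg.resize(maxNode + 2);
    off.resize(maxNode + 2);
    par.resize(maxNode + 2);
    post.resize(maxNode + 2);
    st.resize((size_t)(maxNode + 2) * nChar);
  }
  if ((int)adj.size() < 2 * nEdge) adj.resize(2 * nEdge);

  std::fill(deg.begin(), deg.begin() + maxNode + 2, 0);
  for (int e = 0; e < nEdge; ++e) {
    deg[edges[2 * e]]++;
    deg[edges[2 * e + 1]]++;
  }
  off[0] = 0;
  for (int v = 0; v <= maxNode; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> cursor(off.begin(), off.begin() + maxNode + 2);
  for (int e = 0; e < nEdge; ++e) {
    int p = edges[2 * e], c = edges[2 * e + 1];
    adj[cursor[p]++] = c;
    adj[cursor[c]++] = p;
  }

  // root at the smallest tip present
  int root = -1;
  for (int v = 1; v <= std::min(nTips, maxNode); ++v)
    if (deg[v] > 0) { root = v; break; }
  if (root < 0) stop("tree has no tip nodes");

  // preorder by DFS, postorder = reverse
  int nNode = 0;
  std::vector<int> stack;
  stack.push_back(root);
  par[root] = 0;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    post[nNode++] = u;
    for (int i = off[u]; i < off[u + 1]; ++i) {
      int v = adj[i];
      if (v != par[u]) { par[v] = u; stack.push_back(v); }
    }
  }

  std::fill(steps_out.begin(), steps_out.end(), 0);
  // downpass in reverse preorder
  for (int idx = nNode - 1; idx >= 0; --idx) {
    int u = post[idx];
    if (u <= nTips) {
      for (int c = 0; c < nChar; ++c)
        st[(size_t)u * nChar + c] = tipStates(u - 1, c);
    } else {
      // fold children sequentially (exactly two for binary trees)
      bool first = true;
      for (int i = off[u]; i < off[u + 1]; ++i) {
        int v = adj[i];
        if (v == par[u]) continue;
        if (first) {
          for (int c = 0; c < nChar; ++c)
            st[(size_t)u * nChar + c] = st[(size_t)v * nChar + c];
          first = false;
        } else {
          for (int c = 0; c < nChar; ++c) {
            int s;
            steps_out[c] += popcount_steps(st[(size_t)u * nChar + c],
                                           st[(size_t)v * nChar + c], s);
            st[(size_t)u * nChar + c] = s;
          }
        }
      }
    }
  }
  // fold the root tip itself against its single child
  int child = -1;
  for (int i = off[root]; i < off[root + 1]; ++i) child = adj[i];
  for (int c = 0; c < nChar; ++c) {
    int s;
    steps_out[c] += popcount_steps(st[(size_t)root * nChar + c],
                                   st[(size_t)child * nChar + c], s);
  }
}

//' @noRd
// [[Rcpp::export(name = ".fitch_batch_cpp")]]
IntegerVector fitch_batch_cpp(IntegerMatrix trees, IntegerMatrix tipStates,
                              int nTips) {
  int nTrees = trees.nrow();
  int twoE = trees.ncol();
  if (twoE % 2 != 0) stop("each tree row must hold (parent, child) pairs");
  int nEdge = twoE / 2;
  int nChar = tipStates.ncol();
  IntegerVector out(nTrees);
  std::vector<int> steps(nChar), deg, off, adj, par, post, st;
  std::vector<int> row(twoE);
  for (int t = 0; t < nTrees; ++t) {
    for (int j = 0; j < twoE; ++j) row[j] = trees(t, j);
    fitch_one(row.data(), nEdge, tipStates, nTips, steps, deg, off, adj, par, post, st);
    int tot = 0;
    for (int c = 0; c < nChar; ++c) tot += steps[c];
    out[t] = tot;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".fitch_chars_cpp")]]
IntegerVector fitch_chars_cpp(IntegerMatrix edges, IntegerMatrix tipStates,
                              int nTips) {
  int nEdge = edges.nrow();
  int nChar = tipStates.ncol();
  std::vector<int> row(2 * nEdge);
  for (int e = 0; e < nEdge; ++e) {
    row[2 * e] = edges(e, 0);
    row[2 * e + 1] = edges(e, 1);
  }
  std::vector<int> steps(nChar), deg, off, adj, par, post, st;
  fitch_one(row.data(), nEdge, tipStates, nTips, steps, deg, off, adj, par, post, st);
  return IntegerVector(steps.begin(), steps.end());
}
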