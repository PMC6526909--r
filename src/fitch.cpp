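#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Tip states are bitmasks over a character's alphabet (bit j = state j
// allowed). Missing / inapplicable cells arrive as the full alphabet mask,
// polymorphic cells as multi-bit masks, so the scorer never distinguishes
// them.
//
// The search scorer packs 4 characters per 32-bit word (7-bit fields with a
// guard bit), grouping characters of equal weight into the same words, so a
// binary Fitch pass handles 4 characters at once. Zero fields after the
// AND are detected with the classic zero-byte trick and replaced by the
// union, counting one step each.

struct TreeIdx {
  int maxnode, root;
  std::vector<int> childStart;   // size maxnode+2
  std::vector<int> childList;    // size nedge
  std::vector<int> postorder;    // internal nodes, children before parents
};

static TreeIdx build_index(const IntegerMatrix &edge, int ntip) {
  int nE = edge.nrow();
  int maxnode = ntip;
  for (int i = 0; i < nE; i++)
    maxnode = std::max(maxnode, std::max(edge(i, 0), edge(i, 1)));
  std::vector<int> nchild(maxnode + 1, 0), par(maxnode + 1, 0);
  for (int i = 0; i < nE; i++) {
    int p = edge(i, 0), c = edge(i, 1);
    if (p < 1 || c < 1) stop("invalid node id in edge matrix");
    nchild[p]++;
    par[c] = p;
  }
  TreeIdx T;
  T.maxnode = maxnode;
  T.childStart.assign(maxnode + 2, 0);
  for (int v = 1; v <= maxnode; v++)
    T.childStart[v + 1] = T.childStart[v] + nchild[v];
  T.childList.assign(nE, 0);
  std::vector<int> fill(maxnode + 1, 0);
  for (int i = 0; i < nE; i++) {
    int p = edge(i, 0);
    T.childList[T.childStart[p] + fill[p]++] = edge(i, 1);
  }
  T.root = -1;
  for (int v = 1; v <= maxnode; v++)
    if (par[v] == 0 && nchild[v] > 0) {
      if (T.root != -1) stop("edge matrix has more than one root");
      T.root = v;
    }
  if (T.root == -1) stop("edge matrix has no root");
  // reverse preorder == valid postorder (children before parents)
  std::vector<int> stack;
  stack.reserve(maxnode);
  std::vector<int> pre;
  pre.reserve(maxnode);
  stack.push_back(T.root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (nchild[v] > 0) pre.push_back(v);
    for (int j = T.childStart[v]; j < T.childStart[v + 1]; j++)
      stack.push_back(T.childList[j]);
  }
  T.postorder.assign(pre.rbegin(), pre.rend());
  return T;
}

// Hartigan pass for one character (handles polytomies); unweighted steps.
static int char_steps(const TreeIdx &T, const int *tipcol, int ntip,
                      std::vector<unsigned int> &mask) {
  for (int t = 1; t <= ntip; t++) mask[t] = (unsigned int)tipcol[t - 1];
  int steps = 0;
  int cnt[32];
  for (size_t q = 0; q < T.postorder.size(); q++) {
    int v = T.postorder[q];
    int a = T.childStart[v], b = T.childStart[v + 1];
    if (b - a == 2) { // Fitch fast path
      unsigned int m1 = mask[T.childList[a]], m2 = mask[T.childList[a + 1]];
      unsigned int in = m1 & m2;
      if (in) mask[v] = in;
      else { mask[v] = m1 | m2; steps++; }
    } else {
      std::fill(cnt, cnt + 32, 0);
      for (int j = a; j < b; j++) {
        unsigned int m = mask[T.childList[j]];
        while (m) { cnt[__builtin_ctz(m)]++; m &= m - 1; }
      }
      int K = 0;
      for (int s = 0; s < 32; s++) K = std::max(K, cnt[s]);
      unsigned int mv = 0;
      for (int s = 0; s < 32; s++)
        if (cnt[s] == K) mv |= (1u << s);
      mask[v] = mv;
      steps += (b - a) - K;
    }
  }
  return steps;
}

// [[Rcpp::export]]
IntegerVector fitch_counts_cpp(IntegerMatrix edge, int ntip, IntegerMatrix bits) {
  if (bits.nrow() != ntip) stop("bits must have one row per tip");
  TreeIdx T = build_index(edge, ntip);
  int nchar = bits.ncol();
  IntegerVector out(nchar);
  std::vector<unsigned int> mask(T.maxnode + 1);
  std::vector<int> col(ntip);
  for (int c = 0; c < nchar; c++) {
    for (int t = 0; t < ntip; t++) col[t] = bits(t, c);
    out[c] = char_steps(T, col.data(), ntip, mask);
  }
  return out;
}

// [[Rcpp::export]]
double fitch_total_cpp(IntegerMatrix edge, int ntip, IntegerMatrix bits,
                       NumericVector w, double bound) {
  if (bits.nrow() != ntip) stop("bits must have one row per tip");
  if (w.size() != bits.ncol()) stop("one weight per character required");
  TreeIdx T = build_index(edge, ntip);
  std::vector<unsigned int> mask(T.maxnode + 1);
  std::vector<int> col(ntip);
  int nchar = bits.ncol();
  double acc = 0.0;
  for (int c = 0; c < nchar; c++) {
    if (w[c] == 0.0) continue;
    for (int t = 0; t < ntip; t++) col[t] = bits(t, c);
    acc += w[c] * char_steps(T, col.data(), ntip, mask);
    if (acc >= bound) return acc;
  }
  return acc;
}

// ---- packed binary-Fitch scoring for the searches ----------------------

static const unsigned int FLSB  = 0x00204081u; // bit 0 of each 7-bit field
static const unsigned int FGUARD = 0x08102040u; // bit 6 of each field
static const unsigned int FDATAM = FGUARD - FLSB; // 0x3F in each field
// exact per-field zero detection: adding 0x3F to a 6-bit field sets the
// guard bit iff the field is nonzero (no carry can cross fields)

struct PackedData {
  int ntip, nwords;
  std::vector<unsigned int> tipw; // word-major: tipw[j*ntip + (t-1)]
  std::vector<double> ww;         // weight per word
};

// group characters by weight, 4 per word; padding fields hold state 0 for
// every tip so they never contribute a step
static PackedData pack_bits(const IntegerMatrix &bits,
                            const NumericVector &w) {
  int ntip = bits.nrow(), nchar = bits.ncol();
  // order characters by weight value
  std::vector<int> ord(nchar);
  for (int i = 0; i < nchar; i++) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return w[a] < w[b]; });
  PackedData D;
  D.ntip = ntip;
  int i = 0;
  while (i < nchar && w[ord[i]] == 0.0) i++;  // drop zero-weight characters
  while (i < nchar) {
    double cw = w[ord[i]];
    int j = i;
    while (j < nchar && w[ord[j]] == cw && j - i < 4) j++;
    std::vector<unsigned int> word(ntip, 0u);
    for (int f = 0; f < 4; f++) {
      if (i + f < j) {
        int c = ord[i + f];
        for (int t = 0; t < ntip; t++) {
          if ((unsigned int)bits(t, c) > 0x3Fu)
            stop("search scoring supports at most 6 states per character");
          word[t] |= ((unsigned int)bits(t, c) & 0x3Fu) << (7 * f);
        }
      } else {
        for (int t = 0; t < ntip; t++)
          word[t] |= 1u << (7 * f);            // pad: constant state 0
      }
    }
    D.tipw.insert(D.tipw.end(), word.begin(), word.end());
    D.ww.push_back(cw);
    i = j;
  }
  D.nwords = (int)D.ww.size();
  return D;
}

// ---- binary trees in parent/child arrays -------------------------------

struct PTree {
  int ntip, nnode_max, root;
  std::vector<int> par, ch1, ch2;
};

static PTree from_edge(const IntegerMatrix &edge, int ntip) {
  int nE = edge.nrow();
  int maxnode = ntip;
  for (int i = 0; i < nE; i++)
    maxnode = std::max(maxnode, std::max(edge(i, 0), edge(i, 1)));
  PTree P;
  P.ntip = ntip;
  P.nnode_max = maxnode;
  P.par.assign(maxnode + 1, 0);
  P.ch1.assign(maxnode + 1, 0);
  P.ch2.assign(maxnode + 1, 0);
  for (int i = 0; i < nE; i++) {
    int p = edge(i, 0), c = edge(i, 1);
    P.par[c] = p;
    if (P.ch1[p] == 0) P.ch1[p] = c;
    else if (P.ch2[p] == 0) P.ch2[p] = c;
    else stop("search requires a fully resolved (binary) tree");
  }
  P.root = -1;
  for (int v = 1; v <= maxnode; v++)
    if (P.par[v] == 0 && P.ch1[v] != 0) P.root = v;
  if (P.root == -1) stop("no root found");
  for (int v = ntip + 1; v <= maxnode; v++)
    if (P.ch1[v] != 0 && P.ch2[v] == 0)
      stop("search requires a fully resolved (binary) tree");
  return P;
}

static void replace_child(PTree &P, int p, int oldc, int newc) {
  if (P.ch1[p] == oldc) P.ch1[p] = newc;
  else if (P.ch2[p] == oldc) P.ch2[p] = newc;
  else stop("internal error: child link broken");
}

static void build_post(const PTree &P, std::vector<int> &stack,
                       std::vector<int> &post) {
  stack.clear();
  post.clear();
  stack.push_back(P.root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (P.ch1[v] != 0) {
      post.push_back(v);
      stack.push_back(P.ch1[v]);
      stack.push_back(P.ch2[v]);
    }
  }
  std::reverse(post.begin(), post.end());
}

static double score_packed(const PTree &P, const PackedData &D, double bound,
                           std::vector<unsigned int> &mask,
                           std::vector<int> &stack, std::vector<int> &post) {
  build_post(P, stack, post);
  const int ntip = P.ntip;
  const int npost = (int)post.size();
  double acc = 0.0;
  for (int j = 0; j < D.nwords; j++) {
    const unsigned int *tp = &D.tipw[(size_t)j * ntip];
    int steps = 0;
    for (int q = 0; q < npost; q++) {
      int v = post[q];
      int c1 = P.ch1[v], c2 = P.ch2[v];
      unsigned int m1 = (c1 <= ntip) ? tp[c1 - 1] : mask[c1];
      unsigned int m2 = (c2 <= ntip) ? tp[c2 - 1] : mask[c2];
      unsigned int in = m1 & m2;
      unsigned int z = ~(in + FDATAM) & FGUARD;
      if (z) {
        unsigned int fm = (z >> 6) * 0x7Fu;
        mask[v] = (in & ~fm) | ((m1 | m2) & fm);
        steps += __builtin_popcount(z);
      } else {
        mask[v] = in;
      }
    }
    acc += D.ww[j] * steps;
    if (acc >= bound) return acc;
  }
  return acc;
}

static IntegerMatrix ptree_edge(const PTree &P) {
  int nE = 0;
  for (int v = 1; v <= P.nnode_max; v++) if (P.par[v] != 0) nE++;
  IntegerMatrix eout(nE, 2);
  int k = 0;
  for (int v = 1; v <= P.nnode_max; v++)
    if (P.par[v] != 0) { eout(k, 0) = P.par[v]; eout(k, 1) = v; k++; }
  return eout;
}

// [[Rcpp::export]]
List spr_search_cpp(IntegerMatrix edge, int ntip, IntegerMatrix bits,
                    NumericVector w) {
  if (bits.nrow() != ntip) stop("bits must have one row per tip");
  if (w.size() != bits.ncol()) stop("one weight per character required");
  PTree P = from_edge(edge, ntip);
  PackedData D = pack_bits(bits, w);
  std::vector<unsigned int> mask(P.nnode_max + 1);
  std::vector<int> stack, post, targets;
  double best = score_packed(P, D, R_PosInf, mask, stack, post);

  const double eps = 1e-9;
  bool improved = true;
  while (improved) {
    improved = false;
    for (int v = 1; v <= P.nnode_max; v++) {
      if (v == P.root) continue;
      int u = P.par[v];
      if (u == 0 || u == P.root) continue; // root edge stays fixed
      int g = P.par[u];
      int s = (P.ch1[u] == v) ? P.ch2[u] : P.ch1[u];
      // detach: g adopts s, u floats (keeping child v)
      replace_child(P, g, u, s);
      P.par[s] = g;
      P.par[u] = 0;
      // enumerate regraft edges (p, x) by traversal from root
      targets.clear();
      stack.clear();
      stack.push_back(P.root);
      while (!stack.empty()) {
        int n = stack.back();
        stack.pop_back();
        if (n != P.root) targets.push_back(n);
        if (P.ch1[n] != 0) { stack.push_back(P.ch1[n]); stack.push_back(P.ch2[n]); }
      }
      bool accepted = false;
      for (size_t t = 0; t < targets.size(); t++) {
        int x = targets[t];
        int p = P.par[x];
        if (x == s && p == g) continue; // original position
        replace_child(P, p, x, u);
        P.par[u] = p;
        P.par[x] = u;
        if (P.ch1[u] == v) P.ch2[u] = x; else P.ch1[u] = x;
        double len = score_packed(P, D, best - eps, mask, stack, post);
        if (len < best - eps) {
          best = len;
          improved = true;
          accepted = true;
          break;            // keep the move, continue sweeping from next v
        }
        P.par[x] = p;       // undo
        replace_child(P, p, u, x);
        P.par[u] = 0;
      }
      if (!accepted) {
        replace_child(P, g, s, u);   // restore original position
        P.par[u] = g;
        P.par[s] = u;
        if (P.ch1[u] == v) P.ch2[u] = s; else P.ch1[u] = s;
      }
    }
  }
  return List::create(_["edge"] = ptree_edge(P), _["length"] = best);
}

// stepwise addition: taxa inserted in the given order, each at the
// insertion point minimizing the packed Fitch length (first best kept)
// [[Rcpp::export]]
List addition_tree_cpp(IntegerVector order, int ntip, IntegerMatrix bits,
                       NumericVector w) {
  if (order.size() != ntip) stop("order must list every tip");
  if (ntip < 3) stop("stepwise addition needs at least 3 taxa");
  PTree P;
  P.ntip = ntip;
  P.nnode_max = 2 * ntip;  // tips + up to ntip-1 internals (ids ntip+1..)
  P.par.assign(P.nnode_max + 1, 0);
  P.ch1.assign(P.nnode_max + 1, 0);
  P.ch2.assign(P.nnode_max + 1, 0);
  int r = ntip + 1, q = ntip + 2;
  int o1 = order[0], o2 = order[1], o3 = order[2];
  P.root = r;
  P.ch1[r] = o1; P.ch2[r] = q; P.par[o1] = r; P.par[q] = r;
  P.ch1[q] = o2; P.ch2[q] = o3; P.par[o2] = q; P.par[o3] = q;
  int next_id = ntip + 3;

  PackedData D = pack_bits(bits, w);
  std::vector<unsigned int> mask(P.nnode_max + 1);
  std::vector<int> stack, post, nodes;
  nodes.push_back(o1); nodes.push_back(o2); nodes.push_back(o3);
  nodes.push_back(r); nodes.push_back(q);

  for (int k = 3; k < ntip; k++) {
    int tnew = order[k];
    int j = next_id++;
    double best = R_PosInf;
    int best_x = -1;
    for (size_t ix = 0; ix < nodes.size(); ix++) {
      int x = nodes[ix];
      int p = P.par[x];
      // insert junction j on edge (p, x); if x is root, j becomes root
      P.par[j] = p;
      if (p != 0) replace_child(P, p, x, j); else P.root = j;
      P.par[x] = j;
      P.ch1[j] = x; P.ch2[j] = tnew; P.par[tnew] = j;
      double len = score_packed(P, D, best, mask, stack, post);
      if (len < best - 1e-9) { best = len; best_x = x; }
      // undo
      P.par[x] = p;
      if (p != 0) replace_child(P, p, j, x); else P.root = x;
      P.par[j] = 0; P.ch1[j] = 0; P.ch2[j] = 0; P.par[tnew] = 0;
    }
    // apply best insertion
    int x = best_x, p = P.par[x];
    P.par[j] = p;
    if (p != 0) replace_child(P, p, x, j); else P.root = j;
    P.par[x] = j;
    P.ch1[j] = x; P.ch2[j] = tnew; P.par[tnew] = j;
    nodes.push_back(tnew);
    nodes.push_back(j);
  }
  double len = score_packed(P, D, R_PosInf, mask, stack, post);
  return List::create(_["edge"] = ptree_edge(P), _["length"] = len);
}
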