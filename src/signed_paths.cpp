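// Exact maximum-magnitude signed edge-weight-product simple paths.
//
// For a source s and every target t we want
//   gain(s,t): the maximum product of edge weights over simple paths whose
//              product is positive (0 if none exists), and
//   loss(s,t): the most negative product over simple paths whose product is
//              negative (0 if none exists),
// plus one deterministic witness path per nonzero value.
//
// Because |w| <= 1 extending a path never increases the product magnitude,
// so a best-first (Dijkstra-like) frontier ordered by magnitude settles each
// (node, sign) slot at its optimum on first pop.  A single label per
// (node, sign) is not enough, though: the optimal path to t may have a
// prefix that is suboptimal at an intermediate node, and walks through
// negative cycles could otherwise fabricate sign flips.  We therefore keep,
// per (node, sign), a dominance-pruned Pareto set of labels
// (magnitude, visited-set): a label is dropped iff a stored label has
// magnitude >= and visited-set contained in the candidate's.  This keeps the
// search exact over simple paths.
//
// Ties ("equal" = within 1e-9 relative magnitude) among witness paths are
// broken by fewer edges, then lexicographically smallest node sequence
// (node indices are assigned in lexicographic id order on the R side).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const double TIE_TOL = 1e-9;
static const R_xlen_t MAX_LABELS = 5000000;

struct Mask {
  std::vector<uint64_t> w;
  explicit Mask(int nwords) : w(nwords, 0) {}
  inline void set(int i) { w[i >> 6] |= (uint64_t(1) << (i & 63)); }
  inline bool has(int i) const { return (w[i >> 6] >> (i & 63)) & 1; }
  inline bool subset_of(const Mask& o) const {
    for (size_t k = 0; k < w.size(); ++k)
      if (w[k] & ~o.w[k]) return false;
    return true;
  }
};

struct Label {
  double mag;     // product magnitude, in (0, 1]
  int node;       // head of the path
  int sign;       // +1 or -1
  int len;        // number of edges
  int parent;     // arena index of predecessor label, -1 for source
  bool dead;      // evicted by a dominating label
  Mask mask;      // visited vertex set
};

struct HeapEntry {
  double mag;
  int len;
  R_xlen_t idx;
};
struct HeapCmp {
  // max-heap on magnitude; among equal, fewer edges first, then insertion order
  bool operator()(const HeapEntry& a, const HeapEntry& b) const {
    if (a.mag != b.mag) return a.mag < b.mag;
    if (a.len != b.len) return a.len > b.len;
    return a.idx > b.idx;
  }
};

static inline bool mag_tie(double a, double b) {
  double scale = std::max(1.0, std::max(std::fabs(a), std::fabs(b)));
  return std::fabs(a - b) <= TIE_TOL * scale;
}

static std::vector<int> reconstruct(const std::vector<Label>& arena, R_xlen_t idx) {
  std::vector<int> path;
  for (R_xlen_t k = idx; k >= 0; k = arena[k].parent) path.push_back(arena[k].node);
  std::reverse(path.begin(), path.end());
  return path;
}

// lexicographic comparison of node sequences; true if a < b
static bool path_lex_less(const std::vector<int>& a, const std::vector<int>& b) {
  return std::lexicographical_compare(a.begin(), a.end(), b.begin(), b.end());
}

struct SlotResult {
  bool settled = false;
  double mag = 0.0;
  std::vector<int> witness;
};

// Single-source search. adj[u] lists (v, w).  `width` caps the number of
// surviving labels per (node, sign) slot: 0 means unlimited (exact over
// simple paths, exponential worst case), a finite width gives the bounded
// label-correcting search (the per-slot optimum is still found whenever the
// optimal path's prefixes survive at their own slots).
static void search_from(int n, const std::vector<std::vector<std::pair<int,double>>>& adj,
                        int s, SlotResult* pos, SlotResult* neg, int width) {
  const int nwords = (n + 63) / 64;
  std::vector<Label> arena;
  arena.reserve(1024);
  std::priority_queue<HeapEntry, std::vector<HeapEntry>, HeapCmp> heap;
  // Pareto stores: per node, per sign-class (0 = +, 1 = -), arena indices
  std::vector<std::vector<R_xlen_t>> store(2 * n);

  Mask m0(nwords);
  m0.set(s);
  arena.push_back(Label{1.0, s, +1, 0, -1, false, m0});
  heap.push(HeapEntry{1.0, 0, 0});
  store[2 * s + 0].push_back(0);

  while (!heap.empty()) {
    HeapEntry top = heap.top();
    heap.pop();
    Label& cur = arena[top.idx];
    if (cur.dead) continue;
    const int u = cur.node;
    SlotResult* res = (cur.sign > 0) ? &pos[u] : &neg[u];
    if (!res->settled) {
      res->settled = true;
      res->mag = cur.mag;
      res->witness = reconstruct(arena, top.idx);
    } else if (mag_tie(cur.mag, res->mag)) {
      // co-optimal: prefer fewer edges, then lexicographically smaller path
      if (cur.len + 1 < (int)res->witness.size()) {
        res->witness = reconstruct(arena, top.idx);
      } else if (cur.len + 1 == (int)res->witness.size()) {
        std::vector<int> cand = reconstruct(arena, top.idx);
        if (path_lex_less(cand, res->witness)) res->witness = cand;
      }
    }
    // expand
    const double cmag = cur.mag;
    const int csign = cur.sign, clen = cur.len;
    for (const auto& e : adj[u]) {
      const int v = e.first;
      if (arena[top.idx].mask.has(v)) continue;
      const double w = e.second;
      const double nmag = cmag * std::fabs(w);
      const int nsign = (w < 0) ? -csign : csign;
      const int slot = 2 * v + (nsign > 0 ? 0 : 1);
      // dominance check
      bool dominated = false;
      Mask nmask = arena[top.idx].mask;
      nmask.set(v);
      auto& st = store[slot];
      for (size_t k = 0; k < st.size() && !dominated; ++k) {
        const Label& o = arena[st[k]];
        if (o.dead) continue;
        if (o.mag >= nmag && o.mask.subset_of(nmask)) {
          if (o.mag == nmag && o.len == clen + 1 &&
              o.mask.w == nmask.w) {
            // exact twin (same value, length, vertex set): keep lex-smaller
            std::vector<int> oldp = reconstruct(arena, st[k]);
            std::vector<int> cand = reconstruct(arena, top.idx);
            cand.push_back(v);
            if (!path_lex_less(cand, oldp)) dominated = true;
            // if cand is lex-smaller, fall through and insert it; the twin
            // will be evicted by the sweep below
          } else {
            dominated = true;
          }
        }
      }
      if (dominated) continue;
      // evict stored labels the newcomer dominates
      R_xlen_t nidx = (R_xlen_t)arena.size();
      for (size_t k = 0; k < st.size();) {
        Label& o = arena[st[k]];
        if (!o.dead && nmag >= o.mag && nmask.subset_of(o.mask) &&
            !(nmag == o.mag && nmask.w == o.mask.w && o.len <= clen)) {
          o.dead = true;
        }
        if (o.dead) { st[k] = st.back(); st.pop_back(); } else { ++k; }
      }
      if (nidx >= MAX_LABELS)
        stop("signed path search exceeded the label budget; network too dense");
      arena.push_back(Label{nmag, v, nsign, clen + 1, (int)top.idx, false, nmask});
      st.push_back(nidx);
      heap.push(HeapEntry{nmag, clen + 1, nidx});
      if (width > 0 && (int)st.size() > width) {
        // evict the weakest surviving label: smallest magnitude, then
        // longest path, then latest insertion (deterministic)
        size_t worst = 0;
        for (size_t k = 1; k < st.size(); ++k) {
          const Label& a = arena[st[k]];
          const Label& b = arena[st[worst]];
          if (a.mag < b.mag ||
              (a.mag == b.mag && (a.len > b.len ||
                                  (a.len == b.len && st[k] > st[worst]))))
            worst = k;
        }
        arena[st[worst]].dead = true;
        st[worst] = st.back();
        st.pop_back();
      }
    }
  }
}

// Build adjacency from 1-based edge endpoint vectors.
static std::vector<std::vector<std::pair<int,double>>>
build_adj(int n, const IntegerVector& ei, const IntegerVector& ej, const NumericVector& w) {
  std::vector<std::vector<std::pair<int,double>>> adj(n);
  for (R_xlen_t k = 0; k < ei.size(); ++k) {
    int a = ei[k] - 1, b = ej[k] - 1;
    adj[a].push_back({b, w[k]});
    adj[b].push_back({a, w[k]});
  }
  // deterministic expansion order: neighbours in lexicographic (index) order
  for (int u = 0; u < n; ++u)
    std::sort(adj[u].begin(), adj[u].end(),
              [](const std::pair<int,double>& x, const std::pair<int,double>& y) {
                return x.first < y.first;
              });
  return adj;
}

static IntegerVector path_to_R(const std::vector<int>& p) {
  IntegerVector out(p.size());
  for (size_t i = 0; i < p.size(); ++i) out[i] = p[i] + 1;
  return out;
}

// [[Rcpp::export(name = ".cpp_single_source")]]
List cpp_single_source(int n, IntegerVector ei, IntegerVector ej, NumericVector w,
                       int source, int width) {
  auto adj = build_adj(n, ei, ej, w);
  std::vector<SlotResult> pos(n), neg(n);
  search_from(n, adj, source - 1, pos.data(), neg.data(), width);
  NumericVector gain(n), loss(n);
  List wpos(n), wneg(n);
  for (int t = 0; t < n; ++t) {
    if (t == source - 1) { gain[t] = 0.0; loss[t] = 0.0; continue; }
    if (pos[t].settled) { gain[t] = pos[t].mag; wpos[t] = path_to_R(pos[t].witness); }
    if (neg[t].settled) { loss[t] = -neg[t].mag; wneg[t] = path_to_R(neg[t].witness); }
  }
  return List::create(_["gain"] = gain, _["loss"] = loss,
                      _["witness_pos"] = wpos, _["witness_neg"] = wneg);
}

// All pairs: run from every source; the canonical result for pair (i, j)
// with i < j is taken from source i (node indices are in lexicographic id
// order, so this fixes the witness direction deterministically).
// [[Rcpp::export(name = ".cpp_all_pairs")]]
List cpp_all_pairs(int n, IntegerVector ei, IntegerVector ej, NumericVector w, int width) {
  auto adj = build_adj(n, ei, ej, w);
  NumericMatrix G(n, n), L(n, n);
  R_xlen_t npairs = (R_xlen_t)n * (n - 1) / 2;
  List wpos(npairs), wneg(npairs);
  std::vector<SlotResult> pos(n), neg(n);
  R_xlen_t k = 0;
  for (int s = 0; s < n; ++s) {
    if (s < n - 1) {
      for (int t = 0; t < n; ++t) { pos[t] = SlotResult(); neg[t] = SlotResult(); }
      search_from(n, adj, s, pos.data(), neg.data(), width);
    }
    for (int t = s + 1; t < n; ++t, ++k) {
      if (pos[t].settled) {
        G(s, t) = G(t, s) = pos[t].mag;
        wpos[k] = path_to_R(pos[t].witness);
      }
      if (neg[t].settled) {
        L(s, t) = L(t, s) = -neg[t].mag;
        wneg[k] = path_to_R(neg[t].witness);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["G"] = G, _["L"] = L,
                      _["witness_pos"] = wpos, _["witness_neg"] = wneg);
}
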