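// Exact minimum dominating set by branch-and-bound over the set-cover
// integer program: branch on the closed neighborhood of the currently
// hardest-to-dominate vertex (some member of N[v] must enter any dominating
// set), bound with a greedy incumbent, the covering lower bound
// ceil(undominated / max coverage), and a disjoint-neighborhood packing
// bound (vertices with pairwise disjoint allowed-dominator sets each need
// their own dominator). Bitset neighborhoods keep the inner loops cheap.

#include <Rcpp.h>
#include <algorithm>
#include <chrono>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

typedef std::vector<uint64_t> Bits;

inline int popcount_word(uint64_t word) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(word);
#else
  int c = 0;
  while (word) { c += word & 1; word >>= 1; }
  return c;
#endif
}

inline int popcount_vec(const Bits &v) {
  int c = 0;
  for (uint64_t word : v) c += popcount_word(word);
  return c;
}

struct Solver {
  int n, w;
  std::vector<Bits> nb;         // closed neighborhood bitsets
  std::vector<int> best;        // incumbent (vertex indices)
  bool optimal;
  std::chrono::steady_clock::time_point deadline;
  bool has_deadline;
  long long ticks;

  bool time_up() {
    if (!has_deadline) return false;
    if ((++ticks & 2047) != 0) return false;
    return std::chrono::steady_clock::now() > deadline;
  }

  int cover_count(int u, const Bits &dom) const {
    int c = 0;
    for (int k = 0; k < w; ++k) c += popcount_word(nb[u][k] & ~dom[k]);
    return c;
  }

  void greedy_incumbent() {
    Bits dom(w, 0);
    int undominated = n;
    best.clear();
    while (undominated > 0) {
      int pick = -1, pick_cover = -1;
      for (int u = 0; u < n; ++u) {
        int c = cover_count(u, dom);
        if (c > pick_cover) { pick_cover = c; pick = u; }
      }
      best.push_back(pick);
      for (int k = 0; k < w; ++k) dom[k] |= nb[pick][k];
      undominated -= pick_cover;
    }
    improve_incumbent();
  }

  bool dominates(const std::vector<int> &set) const {
    Bits dom(w, 0);
    for (int u : set) {
      for (int k = 0; k < w; ++k) dom[k] |= nb[u][k];
    }
    int covered = popcount_vec(dom);
    return covered == n;
  }

  // Local search on the incumbent: drop redundant members, then try to
  // replace any pair of members with a single vertex. Repeated to a fixed
  // point; keeps the incumbent dominating at all times.
  void improve_incumbent() {
    bool changed = true;
    while (changed) {
      changed = false;
      // shrink: remove redundant members
      for (size_t i = 0; i < best.size(); ++i) {
        std::vector<int> trial;
        for (size_t j = 0; j < best.size(); ++j) {
          if (j != i) trial.push_back(best[j]);
        }
        if (dominates(trial)) {
          best = trial;
          changed = true;
          break;
        }
      }
      if (changed) continue;
      // 2-for-1: replace members {i, j} by one vertex covering their share
      for (size_t i = 0; i < best.size() && !changed; ++i) {
        for (size_t j = i + 1; j < best.size() && !changed; ++j) {
          Bits dom_rest(w, 0);
          for (size_t t = 0; t < best.size(); ++t) {
            if (t == i || t == j) continue;
            for (int k = 0; k < w; ++k) dom_rest[k] |= nb[best[t]][k];
          }
          Bits need(w, 0);
          bool any = false;
          for (int k = 0; k < w; ++k) {
            need[k] = ~dom_rest[k];
            if (k == w - 1 && (n & 63)) need[k] &= (1ULL << (n & 63)) - 1;
            if (need[k]) any = true;
          }
          if (!any) continue;
          for (int u = 0; u < n; ++u) {
            bool covers = true;
            for (int k = 0; k < w; ++k) {
              if (need[k] & ~nb[u][k]) { covers = false; break; }
            }
            if (covers) {
              std::vector<int> trial;
              for (size_t t = 0; t < best.size(); ++t) {
                if (t != i && t != j) trial.push_back(best[t]);
              }
              trial.push_back(u);
              best = trial;
              changed = true;
              break;
            }
          }
        }
      }
    }
  }

  // One dual-ascent pass over `order`; returns the dual objective.
  double dual_pass(const std::vector<int> &order, const Bits &dom,
                   const Bits &forb) const {
    std::vector<double> slack(n, 1.0);
    double total = 0.0;
    for (int v : order) {
      if (dom[v >> 6] & (1ULL << (v & 63))) continue;
      double y = 1.0;
      for (int k = 0; k < w && y > 0.0; ++k) {
        uint64_t word = nb[v][k] & ~forb[k];
        while (word) {
          int u = (k << 6) + __builtin_ctzll(word);
          word &= word - 1;
          if (slack[u] < y) y = slack[u];
        }
      }
      if (y <= 0.0) continue;
      total += y;
      for (int k = 0; k < w; ++k) {
        uint64_t word = nb[v][k] & ~forb[k];
        while (word) {
          int u = (k << 6) + __builtin_ctzll(word);
          word &= word - 1;
          slack[u] -= y;
        }
      }
    }
    return total;
  }

  // Root bound: max dual over many deterministic orderings.
  double root_dual_bound(const Bits &dom, const Bits &forb, int n_orders) {
    std::vector<std::pair<int, int>> scarce;
    for (int v = 0; v < n; ++v) {
      if (dom[v >> 6] & (1ULL << (v & 63))) continue;
      int c = 0;
      for (int k = 0; k < w; ++k) c += popcount_word(nb[v][k] & ~forb[k]);
      scarce.push_back({c, v});
    }
    std::sort(scarce.begin(), scarce.end());
    std::vector<int> order;
    for (auto &pr : scarce) order.push_back(pr.second);
    double bound = dual_pass(order, dom, forb);
    uint64_t state = 0x9E3779B97F4A7C15ULL;   // fixed-seed xorshift
    auto rnd = [&state]() {
      state ^= state << 13; state ^= state >> 7; state ^= state << 17;
      return state;
    };
    for (int t = 0; t < n_orders; ++t) {
      for (size_t i = order.size(); i > 1; --i) {
        std::swap(order[i - 1], order[rnd() % i]);
      }
      double b = dual_pass(order, dom, forb);
      if (b > bound) bound = b;
    }
    return bound;
  }

  // Lagrangian bound for the covering LP at the root:
  // L(lambda) = sum(lambda) - sum_u max(0, sum_{v in N[u]} lambda_v - 1)
  // is a valid lower bound for any lambda >= 0; projected subgradient
  // ascent pushes it toward the LP optimum. Deterministic.
  double lagrangian_bound(const Bits &dom, const Bits &forb, int iters) {
    std::vector<int> elems;      // undominated vertices (constraints)
    for (int v = 0; v < n; ++v) {
      if (!(dom[v >> 6] & (1ULL << (v & 63)))) elems.push_back(v);
    }
    std::vector<int> cands;      // allowed candidates (variables)
    for (int u = 0; u < n; ++u) {
      if (!(forb[u >> 6] & (1ULL << (u & 63)))) cands.push_back(u);
    }
    std::vector<double> lambda(n, 0.0);
    // warm start from the scarce-first ascent duals
    {
      std::vector<double> slack(n, 1.0);
      std::vector<std::pair<int, int>> scarce;
      for (int v : elems) {
        int c = 0;
        for (int k = 0; k < w; ++k) c += popcount_word(nb[v][k] & ~forb[k]);
        scarce.push_back({c, v});
      }
      std::sort(scarce.begin(), scarce.end());
      for (auto &pr : scarce) {
        int v = pr.second;
        double y = 1.0;
        for (int k = 0; k < w; ++k) {
          uint64_t word = nb[v][k] & ~forb[k];
          while (word) {
            int u = (k << 6) + __builtin_ctzll(word);
            word &= word - 1;
            if (slack[u] < y) y = slack[u];
          }
        }
        if (y <= 0.0) continue;
        lambda[v] = y;
        for (int k = 0; k < w; ++k) {
          uint64_t word = nb[v][k] & ~forb[k];
          while (word) {
            int u = (k << 6) + __builtin_ctzll(word);
            word &= word - 1;
            slack[u] -= y;
          }
        }
      }
    }
    double best_bound = 0.0;
    std::vector<double> load(n, 0.0);   // sum of lambda over N[u]
    std::vector<int> viol;
    for (int it = 0; it < iters; ++it) {
      std::fill(load.begin(), load.end(), 0.0);
      for (int v : elems) {
        if (lambda[v] == 0.0) continue;
        for (int k = 0; k < w; ++k) {
          uint64_t word = nb[v][k] & ~forb[k];
          while (word) {
            int u = (k << 6) + __builtin_ctzll(word);
            word &= word - 1;
            load[u] += lambda[v];
          }
        }
      }
      double obj = 0.0;
      for (int v : elems) obj += lambda[v];
      viol.clear();
      for (int u : cands) {
        if (load[u] > 1.0) { obj -= load[u] - 1.0; viol.push_back(u); }
      }
      if (obj > best_bound) best_bound = obj;
      // subgradient wrt lambda_v: 1 - #{u in N[v]: load[u] > 1}
      double step = 0.2 / std::sqrt((double)(it + 1));
      for (int v : elems) {
        int over = 0;
        for (int k = 0; k < w; ++k) {
          uint64_t word = nb[v][k] & ~forb[k];
          while (word) {
            int u = (k << 6) + __builtin_ctzll(word);
            word &= word - 1;
            if (load[u] > 1.0) ++over;
          }
        }
        lambda[v] += step * (1.0 - over);
        if (lambda[v] < 0.0) lambda[v] = 0.0;
      }
    }
    return best_bound;
  }

  int global_lb = 0;   // proven root lower bound

  void rec(std::vector<int> &chosen, const Bits &dom, Bits &forb) {
    if (!optimal) return;                       // time limit already hit
    if ((int)best.size() <= global_lb) return;  // incumbent provably optimal
    if (time_up()) { optimal = false; return; }
    int undominated = n - popcount_vec(dom);
    if (undominated == 0) {
      if ((int)chosen.size() < (int)best.size()) best = chosen;
      return;
    }
    if ((int)chosen.size() + 1 >= (int)best.size()) return;
    // allowed-dominator sets of undominated vertices
    std::vector<std::pair<int, int>> undom;  // (|D(v)|, v)
    undom.reserve(undominated);
    for (int v = 0; v < n; ++v) {
      if (dom[v >> 6] & (1ULL << (v & 63))) continue;
      int c = 0;
      for (int k = 0; k < w; ++k) c += popcount_word(nb[v][k] & ~forb[k]);
      if (c == 0) return;  // v can no longer be dominated
      undom.push_back({c, v});
    }
    std::sort(undom.begin(), undom.end());
    // dual-ascent lower bound: feasible duals y_v for the covering LP
    // (sum of y over N[u] <= 1 for every candidate u); sum(y) rounded up
    // is a valid bound. Processing scarce vertices first tightens it.
    double dual_total = 0.0;
    {
      std::vector<double> slack(n, 1.0);
      for (auto &pr : undom) {
        int v = pr.second;
        double y = 1.0;
        for (int k = 0; k < w && y > 0.0; ++k) {
          uint64_t word = nb[v][k] & ~forb[k];
          while (word) {
            int u = (k << 6) + __builtin_ctzll(word);
            word &= word - 1;
            if (slack[u] < y) y = slack[u];
            if (y <= 0.0) break;
          }
        }
        if (y <= 0.0) continue;
        dual_total += y;
        for (int k = 0; k < w; ++k) {
          uint64_t word = nb[v][k] & ~forb[k];
          while (word) {
            int u = (k << 6) + __builtin_ctzll(word);
            word &= word - 1;
            slack[u] -= y;
          }
        }
      }
    }
    int lb = (int)chosen.size() + (int)std::ceil(dual_total - 1e-9);
    if (lb >= (int)best.size()) return;
    // branch on the vertex with fewest allowed dominators
    int v_best = undom.front().second;
    std::vector<std::pair<int, int>> cands;  // (-cover, u)
    for (int k = 0; k < w; ++k) {
      uint64_t word = nb[v_best][k] & ~forb[k];
      while (word) {
        int u = (k << 6) + __builtin_ctzll(word);
        word &= word - 1;
        cands.push_back({-cover_count(u, dom), u});
      }
    }
    std::sort(cands.begin(), cands.end());
    std::vector<int> newly_forbidden;
    for (auto &pr : cands) {
      int u = pr.second;
      Bits dom2(dom);
      for (int k = 0; k < w; ++k) dom2[k] |= nb[u][k];
      chosen.push_back(u);
      rec(chosen, dom2, forb);
      chosen.pop_back();
      if (!optimal) break;
      if ((int)chosen.size() + 1 >= (int)best.size()) break;
      forb[u >> 6] |= (1ULL << (u & 63));
      newly_forbidden.push_back(u);
    }
    for (int u : newly_forbidden) forb[u >> 6] &= ~(1ULL << (u & 63));
  }
};

}  // namespace

// [[Rcpp::export]]
List mds_branch_bound(List adjacency, double time_limit) {
  Solver s;
  s.n = adjacency.size();
  s.w = std::max(1, (s.n + 63) / 64);
  s.nb.assign(s.n, Bits(s.w, 0));
  for (int v = 0; v < s.n; ++v) {
    IntegerVector nbr = adjacency[v];  // 1-based, includes v itself
    for (int idx : nbr) {
      int u = idx - 1;
      s.nb[v][u >> 6] |= (1ULL << (u & 63));
    }
  }
  s.optimal = true;
  s.ticks = 0;
  s.has_deadline = R_finite(time_limit);
  if (s.has_deadline) {
    s.deadline = std::chrono::steady_clock::now() +
      std::chrono::milliseconds((long long)(time_limit * 1000.0));
  }
  if (s.n == 0) {
    return List::create(_["members"] = IntegerVector(0),
                        _["optimal"] = true);
  }
  s.greedy_incumbent();
  std::vector<int> chosen;
  Bits dom(s.w, 0);
  Bits forb(s.w, 0);
  // Root reductions (sound for the set-cover view of domination):
  //  - if N[u] is contained in N[v] (v != u), u's coverage is redundant:
  //    forbid u as a candidate (ties broken towards the smaller index);
  //  - if N[v] is contained in N[u] (v != u), any set dominating v also
  //    dominates u: drop u's constraint (mark it pre-satisfied).
  for (int u = 0; u < s.n; ++u) {
    for (int v = 0; v < s.n && u != v; ++v) {
      bool u_sub_v = true, v_sub_u = true;
      for (int k = 0; k < s.w; ++k) {
        if (s.nb[u][k] & ~s.nb[v][k]) u_sub_v = false;
        if (s.nb[v][k] & ~s.nb[u][k]) v_sub_u = false;
        if (!u_sub_v && !v_sub_u) break;
      }
      bool equal = u_sub_v && v_sub_u;
      bool strict_u_sub_v = u_sub_v && (!equal || v < u);
      if (strict_u_sub_v && !(forb[v >> 6] & (1ULL << (v & 63)))) {
        forb[u >> 6] |= (1ULL << (u & 63));
      }
      bool strict_v_sub_u = v_sub_u && (!equal || v < u);
      if (strict_v_sub_u && !(dom[v >> 6] & (1ULL << (v & 63)))) {
        dom[u >> 6] |= (1ULL << (u & 63));
      }
    }
  }
  // strong root bound first: often closes the proof outright
  double root_dual = std::max(s.root_dual_bound(dom, forb, 50),
                              s.lagrangian_bound(dom, forb, 600));
  s.global_lb = (int)std::ceil(root_dual - 1e-9);
  if (s.global_lb < (int)s.best.size()) {
    s.rec(chosen, dom, forb);
  }
  if ((int)s.best.size() <= s.global_lb) s.optimal = true;
  IntegerVector members(s.best.size());
  for (size_t i = 0; i < s.best.size(); ++i) members[i] = s.best[i] + 1;
  return List::create(_["members"] = members, _["optimal"] = s.optimal,
                      _["root_bound"] = root_dual);
}
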