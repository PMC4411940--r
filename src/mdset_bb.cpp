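// Exact minimum dominating set by branch-and-bound on the standard binary
// program: min sum x_v subject to x_v + sum_{w in Gamma(v)} x_w >= 1.
// Set-cover view: candidates are closed neighborhoods N[v]; elements are
// vertices that still need domination. Branching: pick an undominated
// element with the fewest available dominators and branch over them
// (including each in turn while excluding the previously tried ones).
// Bounds: max(ceil(u / max_cover), disjoint closed-neighborhood packing).
// Deterministic throughout: ties resolve to the lowest vertex index.

#include <Rcpp.h>
#include <chrono>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct BB {
  int n;
  std::vector<std::vector<int>> cn;   // closed neighborhoods, sorted
  std::vector<char> dominated;        // element already covered
  std::vector<char> excluded;         // candidate no longer available
  std::vector<int> cover_cnt;         // per candidate: undominated in N[v]
  std::vector<int> freq;              // per element: available dominators
  int undominated;
  std::vector<int> chosen;
  std::vector<int> best;
  bool timed_out = false;
  long long nodes = 0;
  double limit_sec;
  std::chrono::steady_clock::time_point t0;
  std::vector<int> mark;              // scratch for packing bound
  int mark_stamp = 0;
  std::vector<int> elem_order;        // static packing order: small N[e] first

  bool time_up() {
    if (timed_out) return true;
    if ((nodes & 255) == 0) {
      double el = std::chrono::duration<double>(
          std::chrono::steady_clock::now() - t0).count();
      if (el > limit_sec) timed_out = true;
    }
    return timed_out;
  }

  void choose(int v, std::vector<int>& newly) {
    chosen.push_back(v);
    for (int e : cn[v]) {
      if (!dominated[e]) {
        dominated[e] = 1;
        --undominated;
        newly.push_back(e);
        for (int c : cn[e]) --cover_cnt[c];
      }
    }
  }

  void unchoose(const std::vector<int>& newly) {
    chosen.pop_back();
    for (int e : newly) {
      dominated[e] = 0;
      ++undominated;
      for (int c : cn[e]) ++cover_cnt[c];
    }
  }

  void exclude(int v) {
    excluded[v] = 1;
    for (int e : cn[v]) if (!dominated[e]) --freq[e];
  }

  void unexclude(int v) {
    excluded[v] = 0;
    for (int e : cn[v]) if (!dominated[e]) ++freq[e];
  }

  // Lower bound on how many more candidates are needed.
  int lower_bound() {
    int maxcov = 0;
    for (int v = 0; v < n; ++v)
      if (!excluded[v] && cover_cnt[v] > maxcov) maxcov = cover_cnt[v];
    if (maxcov == 0) return undominated > 0 ? n + 1 : 0; // infeasible branch
    int lb1 = (undominated + maxcov - 1) / maxcov;
    // Packing: greedily pick undominated elements whose available dominators
    // are pairwise disjoint; each needs its own pick. Low-degree elements
    // first gives larger packings.
    ++mark_stamp;
    int lb2 = 0;
    for (int e : elem_order) {
      if (dominated[e] || mark[e] == mark_stamp) continue;
      ++lb2;
      for (int c : cn[e]) {
        if (excluded[c]) continue;
        for (int e2 : cn[c]) if (!dominated[e2]) mark[e2] = mark_stamp;
      }
    }
    return std::max(lb1, lb2);
  }

  void greedy_incumbent() {
    std::vector<char> dom(n, 0);
    int u = n;
    std::vector<int> cov(n);
    for (int v = 0; v < n; ++v) cov[v] = (int)cn[v].size();
    std::vector<int> sol;
    while (u > 0) {
      int bestv = -1, bestc = -1;
      for (int v = 0; v < n; ++v)
        if (cov[v] > bestc) { bestc = cov[v]; bestv = v; }
      sol.push_back(bestv);
      for (int e : cn[bestv]) {
        if (!dom[e]) {
          dom[e] = 1; --u;
          for (int c : cn[e]) --cov[c];
        }
      }
    }
    best = sol;
  }

  void search() {
    ++nodes;
    if (time_up()) return;
    if (undominated == 0) {
      if (chosen.size() < best.size()) best = chosen;
      return;
    }
    if ((int)chosen.size() + lower_bound() >= (int)best.size()) return;
    // branch element: undominated, minimum freq, lowest index
    int be = -1, bf = n + 1;
    for (int e = 0; e < n; ++e)
      if (!dominated[e] && freq[e] < bf) { bf = freq[e]; be = e; }
    if (bf == 0) return; // cannot be covered on this branch
    std::vector<int> cands;
    for (int c : cn[be]) if (!excluded[c]) cands.push_back(c);
    // try high-coverage candidates first (stable on index)
    std::stable_sort(cands.begin(), cands.end(),
                     [&](int a, int b) { return cover_cnt[a] > cover_cnt[b]; });
    std::vector<int> newly;
    size_t tried = 0;
    for (int c : cands) {
      newly.clear();
      choose(c, newly);
      search();
      unchoose(newly);
      if (timed_out) break;
      exclude(c);
      ++tried;
      if ((int)chosen.size() + 1 >= (int)best.size()) break; // cannot improve
    }
    for (size_t i = 0; i < tried; ++i) unexclude(cands[i]);
  }
};

} // namespace

// [[Rcpp::export(name = ".mdset_bb")]]
List mdset_bb(List adj, double time_limit) {
  BB bb;
  bb.n = adj.size();
  bb.cn.resize(bb.n);
  for (int v = 0; v < bb.n; ++v) {
    IntegerVector nb = adj[v]; // 0-based neighbor indices
    std::vector<int> c(nb.begin(), nb.end());
    c.push_back(v);
    std::sort(c.begin(), c.end());
    bb.cn[v] = c;
  }
  bb.dominated.assign(bb.n, 0);
  bb.excluded.assign(bb.n, 0);
  bb.cover_cnt.resize(bb.n);
  bb.freq.resize(bb.n);
  for (int v = 0; v < bb.n; ++v) {
    bb.cover_cnt[v] = (int)bb.cn[v].size();
    bb.freq[v] = (int)bb.cn[v].size();
  }
  bb.undominated = bb.n;
  bb.mark.assign(bb.n, 0);
  bb.limit_sec = time_limit;
  bb.t0 = std::chrono::steady_clock::now();
  bb.elem_order.resize(bb.n);
  for (int e = 0; e < bb.n; ++e) bb.elem_order[e] = e;
  std::stable_sort(bb.elem_order.begin(), bb.elem_order.end(),
                   [&](int a, int b) { return bb.cn[a].size() < bb.cn[b].size(); });
  bb.greedy_incumbent();
  // Root reduction: exclude any candidate whose closed neighborhood is
  // contained in a remaining candidate's (swapping u for its witness never
  // worsens a solution). Processed in index order so every element keeps at
  // least one available dominator.
  for (int u = 0; u < bb.n; ++u) {
    for (int v : bb.cn[u]) {
      if (v == u || bb.excluded[v]) continue;
      if (bb.cn[v].size() < bb.cn[u].size()) continue;
      if (bb.cn[v].size() == bb.cn[u].size() && v > u) continue; // tie: keep lower index
      if (std::includes(bb.cn[v].begin(), bb.cn[v].end(),
                        bb.cn[u].begin(), bb.cn[u].end())) {
        bb.exclude(u);
        break;
      }
    }
  }
  int root_lb = bb.n == 0 ? 0 : bb.lower_bound();
  if ((int)bb.best.size() > root_lb) bb.search();
  std::vector<int> members = bb.best;
  std::sort(members.begin(), members.end());
  IntegerVector out(members.size());
  for (size_t i = 0; i < members.size(); ++i) out[i] = members[i] + 1;
  bool optimal = !bb.timed_out;
  return List::create(
      _["members"] = out,
      _["objective"] = (int)members.size(),
      _["optimal"] = optimal,
      _["lower_bound"] = optimal ? (int)members.size() : root_lb,
      _["nodes_explored"] = (double)bb.nodes);
}
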