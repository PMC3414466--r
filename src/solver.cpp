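#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Backtracking search for an integer rating matrix (activities x groups,
// ratings rmin..rmax) such that, for every constraint s, the per-group
// maxima over the constraint's activity rows sum exactly to target[s].
//
// Canonical solution: minimal total rating sum, then lexicographically
// smallest in a caller-supplied cell order. The search runs twice: a
// branch-and-bound pass over a search-friendly cell order to find (and
// prove) the optimal sum, then a first-solution pass in canonical cell
// order with the sum fixed.
//
// Propagation at every node, for each constraint touching the assigned
// cell:
//   * lo[g] = max(assigned max, rmin); hi[g] = rmax while unassigned
//     member cells remain in group g, else lo[g];
//   * prune when sum(lo) > target or sum(hi) < target;
//   * deficit bound: the cheapest way to close D = target - sum(lo) is
//     found by exact enumeration of group subsets (ng <= ~8), charging
//     (lo[g] - rmin) + delta[g] for each raised group; the maximum such
//     cost over all constraints lower-bounds the rating sum still to be
//     spent, which prunes against the sum budget.

struct Problem {
  int na, ng, ns, rmin, rmax, ncells;
  std::vector<int> targets;
  std::vector<std::vector<int>> cons_of_act; // per activity: constraint ids
  std::vector<std::vector<int>> members;     // per constraint: activity ids
};

struct State {
  std::vector<int> cur; // ns x ng, max assigned rating (0 = none)
  std::vector<int> un;  // ns x ng, unassigned member cells
};

static inline int idx(int s, int g, int ng) { return s * ng + g; }

// minimal extra rating (above rmin per cell) constraint s still needs;
// returns -1 when the constraint can no longer be satisfied
static int deficit_cost(const Problem& p, const State& st, int s) {
  int ng = p.ng;
  std::vector<int> lo(ng), head(ng), pen(ng);
  int losum = 0, hisum = 0;
  for (int g = 0; g < ng; ++g) {
    int c = st.cur[idx(s, g, ng)];
    lo[g] = std::max(c, p.rmin);
    losum += lo[g];
    bool open = st.un[idx(s, g, ng)] > 0;
    head[g] = open ? (p.rmax - lo[g]) : 0;
    pen[g] = lo[g] - p.rmin;
    hisum += open ? p.rmax : lo[g];
  }
  int D = p.targets[s] - losum;
  if (D < 0 || hisum < p.targets[s]) return -1;
  if (D == 0) return 0;
  // exact subset enumeration: choose groups to raise, minimise
  // sum(pen) + D subject to sum(head) of chosen >= D
  int best = -1;
  int full = 1 << ng;
  for (int m = 1; m < full; ++m) {
    int h = 0, pn = 0;
    for (int g = 0; g < ng; ++g) {
      if (m & (1 << g)) { h += head[g]; pn += pen[g]; }
    }
    if (h >= D && (best < 0 || pn < best)) best = pn;
  }
  if (best < 0) return -1;
  return D + best;
}

static bool prune(const Problem& p, const State& st, int cur_sum,
                  int rem_cells, int budget) {
  if (cur_sum + rem_cells * p.rmin > budget) return true;
  int worst = 0;
  for (int s = 0; s < p.ns; ++s) {
    int d = deficit_cost(p, st, s);
    if (d < 0) return true;
    if (d > worst) worst = d;
  }
  return cur_sum + rem_cells * p.rmin + worst > budget;
}

struct Searcher {
  const Problem& p;
  const std::vector<int>& cell_act;
  const std::vector<int>& cell_grp;
  std::vector<int> assign;
  State st;
  int budget;          // prune sums strictly above this
  bool stop_at_first;  // lex pass: return the first solution found
  std::vector<int> best_assign;
  int best_sum;
  long long nodes;

  Searcher(const Problem& pp, const std::vector<int>& ca,
           const std::vector<int>& cg)
    : p(pp), cell_act(ca), cell_grp(cg), assign(pp.ncells, 0),
      budget(0), stop_at_first(false), best_sum(-1), nodes(0) {
    st.cur.assign(p.ns * p.ng, 0);
    st.un.assign(p.ns * p.ng, 0);
    for (int s = 0; s < p.ns; ++s)
      for (size_t k = 0; k < p.members[s].size(); ++k)
        for (int g = 0; g < p.ng; ++g)
          st.un[idx(s, g, p.ng)]++;
  }

  // returns true when the search should stop (first-solution mode)
  bool dfs(int pos, int cur_sum) {
    if (++nodes > 200000000LL)
      Rcpp::stop("matrix reconstruction search exceeded its node limit");
    if (pos == p.ncells) {
      // equality is guaranteed by propagation (all un == 0, lo==hi)
      best_assign = assign;
      best_sum = cur_sum;
      if (stop_at_first) return true;
      budget = cur_sum - 1; // branch & bound: look for strictly better
      return false;
    }
    int a = cell_act[pos], g = cell_grp[pos];
    const std::vector<int>& cons = p.cons_of_act[a];
    int rem_after = p.ncells - pos - 1;

    int vmax = std::min(p.rmax, budget - cur_sum - rem_after * p.rmin);
    for (size_t i = 0; i < cons.size(); ++i) {
      int s = cons[i];
      int lo_other = 0;
      for (int gg = 0; gg < p.ng; ++gg)
        if (gg != g) lo_other += std::max(st.cur[idx(s, gg, p.ng)], p.rmin);
      vmax = std::min(vmax, p.targets[s] - lo_other);
    }
    if (vmax < p.rmin) return false;

    for (int v = p.rmin; v <= vmax; ++v) {
      // apply
      std::vector<int> saved_cur(cons.size());
      for (size_t i = 0; i < cons.size(); ++i) {
        int s = cons[i];
        saved_cur[i] = st.cur[idx(s, g, p.ng)];
        if (v > st.cur[idx(s, g, p.ng)]) st.cur[idx(s, g, p.ng)] = v;
        st.un[idx(s, g, p.ng)]--;
      }
      assign[pos] = v;
      bool bad = prune(p, st, cur_sum + v, rem_after, budget);
      if (!bad) {
        if (dfs(pos + 1, cur_sum + v)) return true;
      }
      // undo
      for (size_t i = 0; i < cons.size(); ++i) {
        int s = cons[i];
        st.cur[idx(s, g, p.ng)] = saved_cur[i];
        st.un[idx(s, g, p.ng)]++;
      }
      if (stop_at_first && best_sum >= 0) return true;
    }
    return false;
  }
};

// [[Rcpp::export(name = ".solve_impact_cells")]]
SEXP solve_impact_cells(int na, int ng, int rmin, int rmax,
                        List member_idx, IntegerVector targets,
                        IntegerVector search_act_order) {
  Problem p;
  p.na = na; p.ng = ng; p.rmin = rmin; p.rmax = rmax;
  p.ns = targets.size();
  p.ncells = na * ng;
  p.targets = as<std::vector<int>>(targets);
  p.members.resize(p.ns);
  p.cons_of_act.assign(na, std::vector<int>());
  for (int s = 0; s < p.ns; ++s) {
    IntegerVector m = member_idx[s]; // 1-based activity indices
    for (int k = 0; k < m.size(); ++k) {
      int a = m[k] - 1;
      p.members[s].push_back(a);
      p.cons_of_act[a].push_back(s);
    }
  }

  // search-friendly order (activity-major over the supplied permutation)
  std::vector<int> sa(na), s_act(p.ncells), s_grp(p.ncells);
  for (int i = 0; i < na; ++i) sa[i] = search_act_order[i] - 1;
  for (int i = 0; i < na; ++i)
    for (int g = 0; g < ng; ++g) {
      s_act[i * ng + g] = sa[i];
      s_grp[i * ng + g] = g;
    }

  // phase A: prove the minimal total sum
  Searcher bb(p, s_act, s_grp);
  bb.budget = p.ncells * rmax;
  bb.stop_at_first = false;
  bb.dfs(0, 0);
  if (bb.best_sum < 0) return R_NilValue;
  int opt = bb.best_sum;

  // phase B: lexicographically smallest solution at the optimal sum,
  // canonical (catalog) cell order
  std::vector<int> c_act(p.ncells), c_grp(p.ncells);
  for (int i = 0; i < na; ++i)
    for (int g = 0; g < ng; ++g) {
      c_act[i * ng + g] = i;
      c_grp[i * ng + g] = g;
    }
  Searcher lex(p, c_act, c_grp);
  lex.budget = opt;
  lex.stop_at_first = true;
  lex.dfs(0, 0);

  IntegerMatrix out(na, ng);
  for (int pos = 0; pos < p.ncells; ++pos)
    out(c_act[pos], c_grp[pos]) = lex.best_assign[pos];
  return out;
}
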