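#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Hartigan & Hartigan dip statistic.
//
// The dip of an empirical CDF F_n is the smallest eps such that some unimodal
// CDF G (convex up to its mode, concave after; an atom at the mode is allowed)
// satisfies sup_x |F_n(x) - G(x)| <= eps.  Feasibility at a given eps is
// monotone, so the dip is found by bisection on eps with an exact feasibility
// check:
//
// For a candidate mode at the k-th distinct value, the convex branch must pass
// through the windows [hi_i - 2e, lo_i + 2e] at every earlier knot (lo/hi are
// the lower/upper ECDF corners, e = eps expressed on the deviation scale) and
// the concave branch through every later window; the branches meet at the mode
// where an upward jump is allowed.  The binding quantity on each side is the
// extreme value achievable at the mode: the minimal end value of a convex
// nondecreasing function through windows is the upper envelope of the floor
// values and of lines anchored at each floor with the steepest slope forced by
// any earlier cap (slopes are nondecreasing, so a steep mandatory rise
// persists).  The mode is feasible when the convex branch can end no higher
// than the concave branch can start.  The concave side is the mirror image of
// the convex sweep on the negated, reversed sample.

namespace {

struct Line {
  double x0, y0, s; // y = y0 + s * (x - x0)
  double at(double x) const { return y0 + s * (x - x0); }
};

// Li Chao tree over fixed query positions, maximum envelope
struct LiChao {
  int n = 0;
  const std::vector<double>* xs = nullptr;
  std::vector<Line> tree;
  std::vector<char> used;

  void init(const std::vector<double>& positions) {
    xs = &positions;
    n = (int)positions.size();
    tree.assign(4 * std::max(n, 1), Line{0.0, 0.0, 0.0});
    used.assign(4 * std::max(n, 1), 0);
  }
  void add(Line nw, int node, int l, int r) {
    if (!used[node]) { tree[node] = nw; used[node] = 1; return; }
    int m = (l + r) / 2;
    bool left_better = nw.at((*xs)[l]) > tree[node].at((*xs)[l]);
    bool mid_better = nw.at((*xs)[m]) > tree[node].at((*xs)[m]);
    if (mid_better) std::swap(tree[node], nw);
    if (l == r) return;
    if (left_better != mid_better) add(nw, 2 * node, l, m);
    else add(nw, 2 * node + 1, m + 1, r);
  }
  void add(const Line& nw) { if (n) add(nw, 1, 0, n - 1); }
  double query(int i) const {
    double res = -1e300;
    int node = 1, l = 0, r = n - 1;
    while (true) {
      if (used[node]) res = std::max(res, tree[node].at((*xs)[i]));
      if (l == r) break;
      int m = (l + r) / 2;
      if (i <= m) { node = 2 * node; r = m; }
      else { node = 2 * node + 1; l = m + 1; }
    }
    return res;
  }
};

// workspace for one side sweep
struct SideSweep {
  // prefix_ok[j]: a convex nondecreasing branch exists through all windows at
  //               knots < j, ending below the left-limit cap at knot j
  // gmin[j]:      minimal achievable branch value approaching knot j
  std::vector<char> prefix_ok;
  std::vector<double> gmin;
  LiChao env;
  std::vector<int> hull; // indices of lower hull of cap points (v_i, b_i)

  void run(const std::vector<double>& v, const std::vector<double>& lo,
           const std::vector<double>& hi, double eps) {
    const int K = (int)v.size();
    const double tol = 1e-12;
    prefix_ok.assign(K, 0);
    gmin.assign(K, 0.0);
    env.init(v);
    hull.clear();
    bool ok = true;
    double best_flat = 0.0;
    int nlines = 0;
    for (int j = 0; j < K; ++j) {
      const double a = hi[j] - eps; // value floor at knot j
      const double b = lo[j] + eps; // cap (left-limit and value) at knot j
      double e = best_flat;
      if (nlines) e = std::max(e, env.query(j));
      if (e < 0.0) e = 0.0;
      gmin[j] = e;
      prefix_ok[j] = (ok && e <= b + tol) ? 1 : 0;
      if (a > b + tol || e > b + tol) ok = false;
      // steepest slope forced at knot j by an earlier cap: the maximising cap
      // lies on the lower convex hull of (v_i, b_i); slope to hull vertices is
      // unimodal, located by ternary search
      double s = 0.0;
      if (!hull.empty()) {
        int loI = 0, hiI = (int)hull.size() - 1;
        while (hiI - loI > 2) {
          int m1 = loI + (hiI - loI) / 3, m2 = hiI - (hiI - loI) / 3;
          double f1 = (a - (lo[hull[m1]] + eps)) / (v[j] - v[hull[m1]]);
          double f2 = (a - (lo[hull[m2]] + eps)) / (v[j] - v[hull[m2]]);
          if (f1 < f2) loI = m1 + 1; else hiI = m2;
        }
        for (int t = loI; t <= hiI; ++t) {
          double f = (a - (lo[hull[t]] + eps)) / (v[j] - v[hull[t]]);
          if (f > s) s = f;
        }
      }
      if (s > 0.0 || true) {
        env.add(Line{v[j], a, s});
        ++nlines;
      }
      // extend the lower hull of cap points with (v_j, b_j)
      while (hull.size() >= 2) {
        int p = hull[hull.size() - 2], q = hull[hull.size() - 1];
        double cross = (v[q] - v[p]) * ((lo[j] + eps) - (lo[p] + eps)) -
                       (v[j] - v[p]) * ((lo[q] + eps) - (lo[p] + eps));
        if (cross <= 0.0) hull.pop_back(); else break;
      }
      hull.push_back(j);
      if (a > best_flat) best_flat = a;
    }
  }
};

bool dip_feasible(const std::vector<double>& v, const std::vector<double>& lo,
                  const std::vector<double>& hi,
                  const std::vector<double>& vm, const std::vector<double>& lom,
                  const std::vector<double>& him,
                  double eps, SideSweep& fwd, SideSweep& bwd) {
  const int K = (int)v.size();
  const double tol = 1e-12;
  fwd.run(v, lo, hi, eps);
  bwd.run(vm, lom, him, eps);
  for (int j = 0; j < K; ++j) {
    int jm = K - 1 - j;
    if (!fwd.prefix_ok[j] || !bwd.prefix_ok[jm]) continue;
    double hmax = std::min(1.0 - bwd.gmin[jm], hi[j] + eps);
    double hfloor = hi[j] - eps; // the concave branch owns the value at knot j
    if (hmax + tol >= hfloor && fwd.gmin[j] <= hmax + tol) return true;
  }
  return false;
}

} // namespace

// [[Rcpp::export(name = ".dip_stat_sorted")]]
double dip_stat_sorted(NumericVector xs) {
  const int n = xs.size();
  if (n < 1) stop("empty sample");
  std::vector<double> v, lo, hi;
  v.reserve(n); lo.reserve(n); hi.reserve(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    v.push_back(xs[i]);
    lo.push_back((double)i / n);
    hi.push_back((double)j / n);
    i = j;
  }
  const int K = (int)v.size();
  if (K == 1) return 0.0;
  std::vector<double> vm(K), lom(K), him(K);
  for (int k = 0; k < K; ++k) {
    vm[k] = -v[K - 1 - k];
    lom[k] = 1.0 - hi[K - 1 - k];
    him[k] = 1.0 - lo[K - 1 - k];
  }
  SideSweep fwd, bwd;
  double elo = 0.0, ehi = 0.26; // dip never exceeds 1/4
  for (int it = 0; it < 50; ++it) {
    double mid = 0.5 * (elo + ehi);
    if (dip_feasible(v, lo, hi, vm, lom, him, mid, fwd, bwd)) ehi = mid;
    else elo = mid;
  }
  return 0.5 * (elo + ehi);
}
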