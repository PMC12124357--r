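// Exact Hartigan dip statistic by mode enumeration on distinct values.
//
// The dip of an empirical distribution F_n is the smallest sup-norm
// distance to any unimodal CDF (convex up to the mode m, concave after,
// with an atom permitted only at m).  Candidate modes are each distinct
// data value (the atom there is free) and any position inside a gap
// between adjacent distinct values.  For a fixed mode position the
// minimal distance satisfies linear constraints:
//   * 2d >= deviation of F_n above the greatest convex minorant of the
//     lower step values on the convex side, where the side includes a
//     terminal at the mode position pinned to the local flat ECDF level
//     (its chords extend across the gap);
//   * the mirror condition on the concave side;
//   * a monotone junction: the smallest value reachable at the left
//     terminal must not exceed the largest value reachable at the right
//     start (checked via extremal support lines, resolved by bisection
//     when it binds).
// The gap minimum is quasiconvex in the mode position (the left part is
// nondecreasing, the right part nonincreasing) and is located by a coarse
// grid plus golden-section refinement.  Complexity is O(m^2) per mode
// evaluation, ample for cohort-scale samples.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Collapsed {
  std::vector<double> xs, chi, clo;
  int m;
};

Collapsed collapse(std::vector<double> x) {
  std::sort(x.begin(), x.end());
  Collapsed c;
  const double n = static_cast<double>(x.size());
  size_t i = 0;
  double cum = 0.0;
  while (i < x.size()) {
    size_t j = i;
    while (j < x.size() && x[j] == x[i]) ++j;
    c.xs.push_back(x[i]);
    c.clo.push_back(cum / n);
    cum += static_cast<double>(j - i);
    c.chi.push_back(cum / n);
    i = j;
  }
  c.m = static_cast<int>(c.xs.size());
  return c;
}

thread_local std::vector<int> g_hull;

// max over b < k of chi_b - hull(x_b); hull = lower convex hull of
// {(xs_i, clo_i) : i < k} plus terminal (y, fk), y > xs[k-1].
// Virtual index k denotes the terminal.
double hull_dev_left(const Collapsed& c, int k, double y, double fk) {
  if (k <= 0) return 0.0;
  const int np = k + 1;
  auto PX = [&](int i) { return i < k ? c.xs[i] : y; };
  auto PY = [&](int i) { return i < k ? c.clo[i] : fk; };
  std::vector<int>& hull = g_hull;
  hull.clear();
  hull.push_back(0);
  for (int j = 1; j < np; ++j) {
    while (hull.size() >= 2) {
      const int a = hull[hull.size() - 2], b = hull.back();
      if ((PY(b) - PY(a)) * (PX(j) - PX(b)) <
          (PY(j) - PY(b)) * (PX(b) - PX(a)))
        break;
      hull.pop_back();
    }
    hull.push_back(j);
  }
  double dev = 0.0;
  size_t s = 0;
  for (int b = 0; b < k; ++b) {
    while (s + 2 < hull.size() && PX(hull[s + 1]) <= PX(b)) ++s;
    const int a = hull[s], cc = hull[s + 1];
    double val;
    if (PX(cc) > PX(a)) {
      val = PY(a) + (PY(cc) - PY(a)) * (PX(b) - PX(a)) / (PX(cc) - PX(a));
    } else {
      val = std::min(PY(a), PY(cc));
    }
    const double t = c.chi[b] - val;
    if (t > dev) dev = t;
  }
  return dev;
}

// mirror: max over b >= k of hull(x_b) - clo_b; hull = upper concave hull
// of terminal (y, fk) plus {(xs_i, chi_i) : i >= k}, y < xs[k].
// Reflection x -> -x maps it onto the left case; virtual index nr denotes
// the terminal (rightmost after reflection).
double hull_dev_right(const Collapsed& c, int k, double y, double fk) {
  if (k >= c.m) return 0.0;
  const int nr = c.m - k;
  const int np = nr + 1;
  auto PX = [&](int i) { return i < nr ? -c.xs[c.m - 1 - i] : -y; };
  auto PY = [&](int i) {
    return i < nr ? 1.0 - c.chi[c.m - 1 - i] : 1.0 - fk;
  };
  auto HI = [&](int i) { return 1.0 - c.clo[c.m - 1 - i]; };
  std::vector<int>& hull = g_hull;
  hull.clear();
  hull.push_back(0);
  for (int j = 1; j < np; ++j) {
    while (hull.size() >= 2) {
      const int a = hull[hull.size() - 2], b = hull.back();
      if ((PY(b) - PY(a)) * (PX(j) - PX(b)) <
          (PY(j) - PY(b)) * (PX(b) - PX(a)))
        break;
      hull.pop_back();
    }
    hull.push_back(j);
  }
  double dev = 0.0;
  size_t s = 0;
  for (int b = 0; b < nr; ++b) {
    while (s + 2 < hull.size() && PX(hull[s + 1]) <= PX(b)) ++s;
    const int a = hull[s], cc = hull[s + 1];
    double val;
    if (PX(cc) > PX(a)) {
      val = PY(a) + (PY(cc) - PY(a)) * (PX(b) - PX(a)) / (PX(cc) - PX(a));
    } else {
      val = std::min(PY(a), PY(cc));
    }
    const double t = HI(b) - val;
    if (t > dev) dev = t;
  }
  return dev;
}

// min reachable value at the left terminal (position term_x, lower band
// term_lb); convex side covers point indices [0, kend).
double min_left(const Collapsed& c, int kend, double term_x, double term_lb,
                double d) {
  double best = std::max(0.0, term_lb);
  for (int b = 0; b < kend; ++b) {
    const double lb_b = c.chi[b] - d;
    double s = 0.0;
    for (int a = 0; a < b; ++a) {
      const double sa = (lb_b - (c.clo[a] + d)) / (c.xs[b] - c.xs[a]);
      if (sa > s) s = sa;
    }
    const double v = lb_b + s * (term_x - c.xs[b]);
    if (v > best) best = v;
  }
  return best;
}

// max reachable value at the right start (position term_x, upper band
// term_ub); concave side covers point indices [rstart, m).
double max_right(const Collapsed& c, int rstart, double term_x,
                 double term_ub, double d) {
  double best = std::min(1.0, term_ub);
  for (int b = rstart; b < c.m; ++b) {
    const double ub_b = c.clo[b] + d;
    double s = 0.0;
    for (int cc = b + 1; cc < c.m; ++cc) {
      const double sc = ((c.chi[cc] - d) - ub_b) / (c.xs[cc] - c.xs[b]);
      if (sc > s) s = sc;
    }
    const double v = ub_b - s * (c.xs[b] - term_x);
    if (v < best) best = v;
  }
  return best;
}

// minimal d for one mode: point mode at index idx, or gap mode at
// position y inside gap idx (between points idx-1 and idx).
double mode_value(const Collapsed& c, bool point_mode, int idx, double y) {
  double term_x, L_lo, R_hi;
  int kend, rstart;
  double Ld, Rd;
  if (point_mode) {
    term_x = c.xs[idx];
    L_lo = c.clo[idx];
    R_hi = c.chi[idx];
    kend = idx;
    rstart = idx + 1;
    Ld = hull_dev_left(c, idx, c.xs[idx], c.clo[idx]);
    Rd = hull_dev_right(c, idx + 1, c.xs[idx], c.chi[idx]);
  } else {
    const double fk = c.clo[idx];  // == chi[idx-1], flat level in the gap
    term_x = y;
    L_lo = fk;
    R_hi = fk;
    kend = idx;
    rstart = idx;
    Ld = hull_dev_left(c, idx, y, fk);
    Rd = hull_dev_right(c, idx, y, fk);
  }
  const double base = std::max(Ld, Rd);
  const double d0 = base / 2.0;
  const double lo0 = min_left(c, kend, term_x, L_lo - d0, d0);
  const double hi0 = max_right(c, rstart, term_x, R_hi + d0, d0);
  if (lo0 <= hi0 + 1e-12) return d0;
  double lo_d = d0, hi_d = 0.2500000001;
  if (d0 >= hi_d) return d0;
  for (int it = 0; it < 38; ++it) {
    const double mid = 0.5 * (lo_d + hi_d);
    const double lo = min_left(c, kend, term_x, L_lo - mid, mid);
    const double hi = max_right(c, rstart, term_x, R_hi + mid, mid);
    if (lo <= hi + 1e-12)
      hi_d = mid;
    else
      lo_d = mid;
  }
  return hi_d;
}

double dip_core(std::vector<double> xv) {
  Collapsed c = collapse(std::move(xv));
  if (c.m == 1) return 0.0;
  double best = R_PosInf;
  for (int j = 0; j < c.m; ++j)
    best = std::min(best, mode_value(c, true, j, 0.0));
  const double golden = (std::sqrt(5.0) - 1.0) / 2.0;
  const int grid = 6;
  for (int k = 1; k < c.m; ++k) {
    const double x0 = c.xs[k - 1], x1 = c.xs[k];
    const double w = x1 - x0;
    const double eps = 1e-9 * std::max(w, 1.0);
    const double fk = c.clo[k];
    const double yl = x0 + eps, yr = x1 - eps;
    // the left deviation only grows with the mode position, the right one
    // only shrinks; without the junction the gap optimum sits where the
    // two curves cross (or at an edge)
    const double Ld_l = hull_dev_left(c, k, yl, fk);
    const double Rd_r = hull_dev_right(c, k, yr, fk);
    if (std::max(Ld_l, Rd_r) / 2.0 >= best) continue;
    double ystar;
    if (Ld_l >= hull_dev_right(c, k, yl, fk)) {
      ystar = yl;
    } else if (Rd_r >= hull_dev_left(c, k, yr, fk)) {
      ystar = yr;
    } else {
      double a = yl, b = yr;
      for (int it = 0; it < 48; ++it) {
        const double mid = 0.5 * (a + b);
        if (hull_dev_left(c, k, mid, fk) < hull_dev_right(c, k, mid, fk))
          a = mid;
        else
          b = mid;
      }
      ystar = 0.5 * (a + b);
    }
    const double base_star = std::max(hull_dev_left(c, k, ystar, fk),
                                      hull_dev_right(c, k, ystar, fk));
    const double v_star = mode_value(c, false, k, ystar);
    if (v_star <= base_star / 2.0 + 1e-13) {
      // junction slack: the crossing value is the exact gap minimum
      best = std::min(best, v_star);
      continue;
    }
    // junction binds: fall back to grid + golden section on the full
    // objective (skippable when the possible improvement is negligible)
    best = std::min(best, v_star);
    if (v_star - base_star / 2.0 < 1e-9 || base_star / 2.0 >= best)
      continue;
    int i0 = 0;
    double v0 = R_PosInf;
    for (int g = 0; g < grid; ++g) {
      const double yg = x0 + w * (g + 0.5) / grid;
      const double v = mode_value(c, false, k, yg);
      if (v < v0) {
        v0 = v;
        i0 = g;
      }
    }
    if (v0 < best) best = v0;
    double a = x0 + w * std::max(0, i0 - 1) / static_cast<double>(grid) + eps;
    double b = x0 + w * std::min(grid, i0 + 2) / static_cast<double>(grid) -
               eps;
    double cc = b - golden * (b - a);
    double dd = a + golden * (b - a);
    double fc = mode_value(c, false, k, cc);
    double fd = mode_value(c, false, k, dd);
    for (int it = 0; it < 36; ++it) {
      if (fc < fd) {
        b = dd;
        dd = cc;
        fd = fc;
        cc = b - golden * (b - a);
        fc = mode_value(c, false, k, cc);
      } else {
        a = cc;
        cc = dd;
        fc = fd;
        dd = a + golden * (b - a);
        fd = mode_value(c, false, k, dd);
      }
    }
    best = std::min(best, std::min(fc, fd));
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  if (xv.empty()) stop("empty sample");
  return dip_core(std::move(xv));
}

// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int n_boot) {
  if (n < 1) stop("n must be positive");
  if (n_boot < 1) stop("n_boot must be positive");
  NumericVector out(n_boot);
  std::vector<double> xv(n);
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < n; ++i) xv[i] = R::runif(0.0, 1.0);
    out[b] = dip_core(xv);
  }
  return out;
}
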