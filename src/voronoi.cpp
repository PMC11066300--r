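// Voronoi cells inside a bounding rectangle by iterative half-plane
// clipping: each site's cell starts as the rectangle and is clipped by the
// perpendicular bisector against every other site, nearest first, with an
// early exit once the bisector is farther than the farthest remaining cell
// vertex. Besides areas this records, per surviving polygon edge, which
// neighbouring site generated it, giving the Voronoi adjacency needed for
// density-connected cluster growth, and whether the cell touches the
// rectangle (such cells are unreliable density estimates and are excluded
// from seeding).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Poly {
  std::vector<double> x, y;
  std::vector<int> owner;  // owner[k]: edge from vertex k to k+1 (wrapping); -1 = rectangle border
};

// Clip polygon to the half-plane { p : (p - m) . d <= 0 }, tagging the new
// edge with `j`. Assumes a convex polygon (preserved by construction).
void clip_halfplane(Poly &p, double mx, double my, double dx, double dy,
                    int j, double eps) {
  const size_t n = p.x.size();
  if (n == 0) return;
  std::vector<double> s(n);
  bool any_in = false, any_out = false;
  for (size_t k = 0; k < n; ++k) {
    s[k] = (p.x[k] - mx) * dx + (p.y[k] - my) * dy;
    if (s[k] <= eps) any_in = true; else any_out = true;
  }
  if (!any_out) return;
  if (!any_in) { p.x.clear(); p.y.clear(); p.owner.clear(); return; }
  Poly q;
  q.x.reserve(n + 2); q.y.reserve(n + 2); q.owner.reserve(n + 2);
  for (size_t k = 0; k < n; ++k) {
    size_t k2 = (k + 1) % n;
    bool ain = s[k] <= eps, bin = s[k2] <= eps;
    if (ain && bin) {
      q.x.push_back(p.x[k]); q.y.push_back(p.y[k]); q.owner.push_back(p.owner[k]);
    } else if (ain && !bin) {
      q.x.push_back(p.x[k]); q.y.push_back(p.y[k]); q.owner.push_back(p.owner[k]);
      double t = s[k] / (s[k] - s[k2]);
      q.x.push_back(p.x[k] + t * (p.x[k2] - p.x[k]));
      q.y.push_back(p.y[k] + t * (p.y[k2] - p.y[k]));
      q.owner.push_back(j);  // edge along the bisector up to the re-entry point
    } else if (!ain && bin) {
      double t = s[k] / (s[k] - s[k2]);
      q.x.push_back(p.x[k] + t * (p.x[k2] - p.x[k]));
      q.y.push_back(p.y[k] + t * (p.y[k2] - p.y[k]));
      q.owner.push_back(p.owner[k]);  // remainder of the old edge
    }
  }
  p = q;
}

double shoelace(const Poly &p) {
  double a = 0.0;
  const size_t n = p.x.size();
  for (size_t k = 0; k < n; ++k) {
    size_t k2 = (k + 1) % n;
    a += p.x[k] * p.y[k2] - p.x[k2] * p.y[k];
  }
  return std::fabs(a) / 2.0;
}

}  // namespace

// [[Rcpp::export(name = ".voronoi_cells_cpp")]]
List voronoi_cells_cpp(NumericVector x, NumericVector y,
                       double xmin, double xmax, double ymin, double ymax) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  NumericVector area(n);
  LogicalVector boundary(n);
  List neighbors(n);
  const double diag2 = (xmax - xmin) * (xmax - xmin) + (ymax - ymin) * (ymax - ymin);
  const double eps = 1e-12 * std::sqrt(diag2);

  std::vector<int> ord(n);
  std::vector<double> d2(n);

  for (int i = 0; i < n; ++i) {
    Poly cell;
    cell.x = {xmin, xmax, xmax, xmin};
    cell.y = {ymin, ymin, ymax, ymax};
    cell.owner = {-1, -1, -1, -1};

    for (int j = 0; j < n; ++j) {
      d2[j] = (x[j] - x[i]) * (x[j] - x[i]) + (y[j] - y[i]) * (y[j] - y[i]);
      ord[j] = j;
    }
    d2[i] = -1.0;  // sorts first, skipped below
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return d2[a] < d2[b]; });

    double max_r2 = diag2;  // squared distance from site to farthest vertex
    for (int jj = 0; jj < n; ++jj) {
      int j = ord[jj];
      if (j == i || d2[j] <= 0.0) continue;  // skip self and coincident sites
      if (d2[j] / 4.0 > max_r2) break;       // bisector cannot reach the cell
      double mx = (x[i] + x[j]) / 2.0, my = (y[i] + y[j]) / 2.0;
      clip_halfplane(cell, mx, my, x[j] - x[i], y[j] - y[i], j, eps);
      if (cell.x.empty()) break;
      max_r2 = 0.0;
      for (size_t k = 0; k < cell.x.size(); ++k) {
        double r2 = (cell.x[k] - x[i]) * (cell.x[k] - x[i]) +
                    (cell.y[k] - y[i]) * (cell.y[k] - y[i]);
        if (r2 > max_r2) max_r2 = r2;
      }
    }

    area[i] = shoelace(cell);
    bool on_border = false;
    std::vector<int> nb;
    for (size_t k = 0; k < cell.owner.size(); ++k) {
      if (cell.owner[k] < 0) on_border = true;
      else nb.push_back(cell.owner[k] + 1);  // 1-based
    }
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    boundary[i] = on_border;
    neighbors[i] = IntegerVector(nb.begin(), nb.end());
  }
  return List::create(_["area"] = area, _["on_boundary"] = boundary,
                      _["neighbors"] = neighbors);
}
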