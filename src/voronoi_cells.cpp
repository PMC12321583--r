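#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Clipped 2D Voronoi diagram by iterative half-plane clipping.
//
// Each seed's cell starts as the bounding box [x0,x1] x [y0,y1] and is cut
// by the perpendicular bisector against other seeds in order of increasing
// distance, stopping once half the distance to the next candidate exceeds
// the farthest current vertex (no further cut possible). Every polygon edge
// remembers its origin: a positive value is the 1-based index of the
// neighboring seed whose bisector created it, negative values -1..-4 are
// the box sides (bottom, right, top, left).
//
// Returns a list with per-seed CCW vertex matrices, per-edge sources and
// shoelace areas.
// [[Rcpp::export]]
List voronoi_cells_cpp(NumericVector x, NumericVector y,
                       double x0, double y0, double x1, double y1) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  List verts(n), srcs(n);
  NumericVector areas(n);

  std::vector<int> ord(n);
  std::vector<double> d2all(n);

  for (int i = 0; i < n; ++i) {
    // candidates sorted by squared distance to seed i
    for (int j = 0; j < n; ++j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      d2all[j] = dx * dx + dy * dy;
      ord[j] = j;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return d2all[a] < d2all[b]; });

    std::vector<double> px = {x0, x1, x1, x0};
    std::vector<double> py = {y0, y0, y1, y1};
    std::vector<int> src = {-1, -2, -3, -4};

    double maxd2 = 0.0;
    for (size_t k = 0; k < px.size(); ++k) {
      const double dx = px[k] - x[i], dy = py[k] - y[i];
      maxd2 = std::max(maxd2, dx * dx + dy * dy);
    }

    std::vector<double> qx, qy, f;
    std::vector<int> qsrc;
    for (int jj = 0; jj < n; ++jj) {
      const int j = ord[jj];
      if (j == i) continue;
      if (d2all[j] > 4.0 * maxd2) break;  // bisector cannot reach the cell
      const double ux = x[j] - x[i], uy = y[j] - y[i];
      const double mx = 0.5 * (x[i] + x[j]), my = 0.5 * (y[i] + y[j]);
      const size_t m = px.size();
      f.resize(m);
      bool any_out = false, all_out = true;
      for (size_t k = 0; k < m; ++k) {
        f[k] = (px[k] - mx) * ux + (py[k] - my) * uy;
        if (f[k] > 0) any_out = true; else all_out = false;
      }
      if (!any_out) continue;
      if (all_out) { px.clear(); py.clear(); src.clear(); break; }
      qx.clear(); qy.clear(); qsrc.clear();
      for (size_t k = 0; k < m; ++k) {
        const size_t k2 = (k + 1) % m;
        const bool in1 = f[k] <= 0, in2 = f[k2] <= 0;
        if (in1 && in2) {
          qx.push_back(px[k]); qy.push_back(py[k]); qsrc.push_back(src[k]);
        } else if (in1 && !in2) {
          qx.push_back(px[k]); qy.push_back(py[k]); qsrc.push_back(src[k]);
          const double t = f[k] / (f[k] - f[k2]);
          qx.push_back(px[k] + t * (px[k2] - px[k]));
          qy.push_back(py[k] + t * (py[k2] - py[k]));
          qsrc.push_back(j + 1);  // boundary now runs along the bisector
        } else if (!in1 && in2) {
          const double t = f[k] / (f[k] - f[k2]);
          qx.push_back(px[k] + t * (px[k2] - px[k]));
          qy.push_back(py[k] + t * (py[k2] - py[k]));
          qsrc.push_back(src[k]);  // remainder of the original edge
        }
      }
      px = qx; py = qy; src = qsrc;
      if (px.size() < 3) { px.clear(); py.clear(); src.clear(); break; }
      maxd2 = 0.0;
      for (size_t k = 0; k < px.size(); ++k) {
        const double dx = px[k] - x[i], dy = py[k] - y[i];
        maxd2 = std::max(maxd2, dx * dx + dy * dy);
      }
    }

    const size_t m = px.size();
    NumericMatrix v(m, 2);
    IntegerVector s(m);
    double area = 0.0;
    for (size_t k = 0; k < m; ++k) {
      v(k, 0) = px[k]; v(k, 1) = py[k];
      s[k] = src[k];
      const size_t k2 = (k + 1) % m;
      area += px[k] * py[k2] - px[k2] * py[k];
    }
    verts[i] = v;
    srcs[i] = s;
    areas[i] = 0.5 * area;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["vertices"] = verts, _["edge_source"] = srcs,
                      _["area"] = areas);
}
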