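#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Clipped planar Voronoi tessellation, computed cell by cell.
//
// Each generator's region starts as the bounding rectangle and is cut by the
// perpendicular bisector of every relevant neighbour, visited in order of
// increasing distance through a uniform spatial grid.  A generator j can only
// cut the current region of i if |p_i - p_j| <= 2 * max_k |p_i - v_k| over the
// region's current vertices, which gives a sound early-termination radius.
// This is the cell-based construction used by Voronoi particle codes; it is
// O(m) per cell for locally uniform point sets (m = local neighbour count).

struct Poly {
  // vertices in CCW order; src[k] identifies the cut that produced the edge
  // from vertex k-1 to vertex k (rectangle edges are -1..-4, bisectors are
  // the 0-based index of the opposing generator)
  std::vector<double> x, y;
  std::vector<int> src;
};

static const double EDGE_EPS = 1e-9;

// Cut poly by the half-plane of points closer to (px,py) than to (qx,qy).
// Returns false if the polygon vanishes.
static bool clip_bisector(Poly &P, double px, double py, double qx, double qy,
                          int j) {
  double dx = qx - px, dy = qy - py;
  double mx = 0.5 * (px + qx), my = 0.5 * (py + qy);
  size_t n = P.x.size();
  if (n == 0) return false;
  std::vector<double> f(n);
  bool any_in = false, any_out = false;
  for (size_t k = 0; k < n; ++k) {
    f[k] = (P.x[k] - mx) * dx + (P.y[k] - my) * dy;  // <=0 : keep
    if (f[k] <= 0) any_in = true; else any_out = true;
  }
  if (!any_out) return true;   // untouched
  if (!any_in) { P.x.clear(); P.y.clear(); P.src.clear(); return false; }

  Poly Q;
  Q.x.reserve(n + 2); Q.y.reserve(n + 2); Q.src.reserve(n + 2);
  for (size_t k = 0; k < n; ++k) {
    size_t km = (k == 0) ? n - 1 : k - 1;
    bool in_prev = f[km] <= 0, in_cur = f[k] <= 0;
    // edge from vertex km to vertex k carries source P.src[k]
    if (in_prev && in_cur) {
      Q.x.push_back(P.x[k]); Q.y.push_back(P.y[k]); Q.src.push_back(P.src[k]);
    } else if (in_prev && !in_cur) {
      double t = f[km] / (f[km] - f[k]);
      Q.x.push_back(P.x[km] + t * (P.x[k] - P.x[km]));
      Q.y.push_back(P.y[km] + t * (P.y[k] - P.y[km]));
      Q.src.push_back(P.src[k]);
    } else if (!in_prev && in_cur) {
      double t = f[km] / (f[km] - f[k]);
      Q.x.push_back(P.x[km] + t * (P.x[k] - P.x[km]));
      Q.y.push_back(P.y[km] + t * (P.y[k] - P.y[km]));
      Q.src.push_back(j);  // entering edge lies on the new bisector
      Q.x.push_back(P.x[k]); Q.y.push_back(P.y[k]); Q.src.push_back(P.src[k]);
    }
  }
  P = std::move(Q);
  return P.x.size() >= 3;
}

static double max_vertex_dist2(const Poly &P, double px, double py) {
  double m = 0.0;
  for (size_t k = 0; k < P.x.size(); ++k) {
    double d2 = (P.x[k] - px) * (P.x[k] - px) + (P.y[k] - py) * (P.y[k] - py);
    if (d2 > m) m = d2;
  }
  return m;
}

// [[Rcpp::export]]
List voronoi_cells_cpp(NumericVector x, NumericVector y, double xmin,
                       double xmax, double ymin, double ymax,
                       bool return_polygons) {
  int n = x.size();
  double W = xmax - xmin, H = ymax - ymin;

  // uniform bucket grid over the rectangle
  int gx = std::max(1, (int)std::round(std::sqrt((double)n * W / std::max(H, 1e-12))));
  int gy = std::max(1, (int)std::round(std::sqrt((double)n * H / std::max(W, 1e-12))));
  double cw = W / gx, ch = H / gy;
  if (cw <= 0) cw = 1; if (ch <= 0) ch = 1;
  auto cell_of = [&](double xx, double yy) {
    int cx = (int)std::floor((xx - xmin) / cw);
    int cy = (int)std::floor((yy - ymin) / ch);
    cx = std::min(std::max(cx, 0), gx - 1);
    cy = std::min(std::max(cy, 0), gy - 1);
    return cy * gx + cx;
  };
  int ncell = gx * gy;
  std::vector<int> cnt(ncell + 1, 0), order(n), cidx(n);
  for (int i = 0; i < n; ++i) { cidx[i] = cell_of(x[i], y[i]); cnt[cidx[i] + 1]++; }
  for (int c = 0; c < ncell; ++c) cnt[c + 1] += cnt[c];
  {
    std::vector<int> pos(cnt.begin(), cnt.end() - 1);
    for (int i = 0; i < n; ++i) order[pos[cidx[i]]++] = i;
  }

  NumericVector area(n), perim(n);
  LogicalVector touches(n);
  List nb(n);
  List polys(return_polygons ? n : 0);

  std::vector<std::pair<double, int>> cand;
  for (int i = 0; i < n; ++i) {
    Poly P;
    P.x = {xmin, xmax, xmax, xmin};
    P.y = {ymin, ymin, ymax, ymax};
    P.src = {-4, -1, -2, -3};  // edge into vertex k (left, bottom, right, top)
    double px = x[i], py = y[i];
    int ci = cidx[i] % gx, cj = cidx[i] / gx;
    double R2 = max_vertex_dist2(P, px, py);
    bool alive = true;

    for (int ring = 0; alive; ++ring) {
      // minimal possible distance from p_i to a point in ring > ring-1 cells away
      if (ring >= 2) {
        double dmin = (ring - 1) * std::min(cw, ch);
        if (dmin * dmin > 4.0 * R2) break;
      }
      int lo_x = ci - ring, hi_x = ci + ring, lo_y = cj - ring, hi_y = cj + ring;
      bool any_cell = false;
      cand.clear();
      for (int cy = lo_y; cy <= hi_y; ++cy) {
        if (cy < 0 || cy >= gy) continue;
        for (int cx = lo_x; cx <= hi_x; ++cx) {
          if (cx < 0 || cx >= gx) continue;
          if (ring > 0 && cx != lo_x && cx != hi_x && cy != lo_y && cy != hi_y)
            continue;  // interior of ring already visited
          any_cell = true;
          int c = cy * gx + cx;
          for (int k = cnt[c]; k < cnt[c + 1]; ++k) {
            int j = order[k];
            if (j == i) continue;
            double d2 = (x[j] - px) * (x[j] - px) + (y[j] - py) * (y[j] - py);
            cand.push_back({d2, j});
          }
        }
      }
      if (!any_cell && ring > std::max(gx, gy)) break;
      std::sort(cand.begin(), cand.end());
      for (auto &pr : cand) {
        if (pr.first > 4.0 * R2) break;
        if (!clip_bisector(P, px, py, x[pr.second], y[pr.second], pr.second)) {
          alive = false;
          break;
        }
        R2 = max_vertex_dist2(P, px, py);
      }
    }

    // measure
    size_t m = P.x.size();
    double A = 0.0, per = 0.0;
    std::vector<int> nbrs;
    bool tch = false;
    for (size_t k = 0; k < m; ++k) {
      size_t km = (k == 0) ? m - 1 : k - 1;
      A += P.x[km] * P.y[k] - P.x[k] * P.y[km];
      double el = std::hypot(P.x[k] - P.x[km], P.y[k] - P.y[km]);
      per += el;
      if (el > EDGE_EPS) {
        if (P.src[k] >= 0) nbrs.push_back(P.src[k] + 1);  // 1-based for R
        else tch = true;
      }
    }
    A = 0.5 * std::fabs(A);
    std::sort(nbrs.begin(), nbrs.end());
    nbrs.erase(std::unique(nbrs.begin(), nbrs.end()), nbrs.end());
    area[i] = A;
    perim[i] = per;
    touches[i] = tch;
    nb[i] = IntegerVector(nbrs.begin(), nbrs.end());
    if (return_polygons) {
      NumericMatrix pm(m, 2);
      for (size_t k = 0; k < m; ++k) { pm(k, 0) = P.x[k]; pm(k, 1) = P.y[k]; }
      polys[i] = pm;
    }
  }

  List out = List::create(_["area"] = area, _["perimeter"] = perim,
                          _["neighbors"] = nb, _["touches_rect"] = touches);
  if (return_polygons) out["polygons"] = polys;
  return out;
}
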