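#include <Rcpp.h>
using namespace Rcpp;

// Euclidean distance from point (px,py) to segment (x0,y0)-(x1,y1),
// with rounded end-caps (true point-to-segment distance).
static inline double seg_dist(double px, double py,
                              double x0, double y0, double x1, double y1) {
  double dx = x1 - x0, dy = y1 - y0;
  double l2 = dx * dx + dy * dy;
  double t = (l2 > 0.0) ? ((px - x0) * dx + (py - y0) * dy) / l2 : 0.0;
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  double qx = x0 + t * dx - px, qy = y0 + t * dy - py;
  return std::sqrt(qx * qx + qy * qy);
}

// Binary raster of pixels whose centre lies within `width` (microns) of a
// polyline given as segment endpoint vectors. Pixel (r,c) (0-based) has its
// centre at ((c + 0.5) * res, (r + 0.5) * res) microns.
// [[Rcpp::export]]
LogicalMatrix cpp_distance_band(int nrow, int ncol, double res,
                                NumericVector x0, NumericVector y0,
                                NumericVector x1, NumericVector y1,
                                double width) {
  LogicalMatrix out(nrow, ncol);
  const int ns = x0.size();
  for (int c = 0; c < ncol; ++c) {
    double px = (c + 0.5) * res;
    for (int r = 0; r < nrow; ++r) {
      double py = (r + 0.5) * res;
      bool in = false;
      for (int s = 0; s < ns; ++s) {
        if (seg_dist(px, py, x0[s], y0[s], x1[s], y1[s]) <= width) {
          in = true;
          break;
        }
      }
      out(r, c) = in;
    }
  }
  return out;
}

static inline bool on_segment(double px, double py,
                              double x0, double y0, double x1, double y1,
                              double eps) {
  double cross = (x1 - x0) * (py - y0) - (y1 - y0) * (px - x0);
  if (std::fabs(cross) > eps) return false;
  double dot = (px - x0) * (x1 - x0) + (py - y0) * (y1 - y0);
  double l2 = (x1 - x0) * (x1 - x0) + (y1 - y0) * (y1 - y0);
  return dot >= -eps && dot <= l2 + eps;
}

static inline bool point_in_poly(double px, double py,
                                 const NumericVector& vx,
                                 const NumericVector& vy,
                                 bool include_boundary, double eps) {
  const int n = vx.size();
  // boundary points count as inside when include_boundary is set
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (on_segment(px, py, vx[j], vy[j], vx[i], vy[i], eps))
      return include_boundary;
  }
  bool inside = false;  // even-odd ray crossing
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if ((vy[i] > py) != (vy[j] > py)) {
      double xint = (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i];
      if (px < xint) inside = !inside;
    }
  }
  return inside;
}

// Rasterise a closed polygon over a pixel grid whose pixel (r,c) centre lies
// at (ox + (c + 0.5) * res, oy + (r + 0.5) * res) microns. Pixel centres
// exactly on an edge are inside iff include_boundary.
// [[Rcpp::export]]
LogicalMatrix cpp_polygon_mask(int nrow, int ncol, double res,
                               double ox, double oy,
                               NumericVector vx, NumericVector vy,
                               bool include_boundary) {
  LogicalMatrix out(nrow, ncol);
  double span = 0.0;
  for (int i = 0; i < vx.size(); ++i)
    span = std::max(span, std::max(std::fabs(vx[i]), std::fabs(vy[i])));
  double eps = 1e-9 * std::max(span, 1.0);
  for (int c = 0; c < ncol; ++c) {
    double px = ox + (c + 0.5) * res;
    for (int r = 0; r < nrow; ++r) {
      double py = oy + (r + 0.5) * res;
      out(r, c) = point_in_poly(px, py, vx, vy, include_boundary, eps);
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector px, NumericVector py,
                                    NumericVector vx, NumericVector vy,
                                    bool include_boundary) {
  const int n = px.size();
  LogicalVector out(n);
  double span = 0.0;
  for (int i = 0; i < vx.size(); ++i)
    span = std::max(span, std::max(std::fabs(vx[i]), std::fabs(vy[i])));
  double eps = 1e-9 * std::max(span, 1.0);
  for (int i = 0; i < n; ++i)
    out[i] = point_in_poly(px[i], py[i], vx, vy, include_boundary, eps);
  return out;
}

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Connected-component labeling of a binary matrix under 8-connectivity.
// Two-pass union-find; labels are 1..k in raster order of first occurrence.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0);  // label 0 = background
  int next = 1;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      // neighbours already visited in raster order (row-major scan)
      int nb[4] = {0, 0, 0, 0};
      int k = 0;
      if (r > 0 && c > 0 && mask(r - 1, c - 1)) nb[k++] = lab(r - 1, c - 1);
      if (r > 0 && mask(r - 1, c)) nb[k++] = lab(r - 1, c);
      if (r > 0 && c < nc - 1 && mask(r - 1, c + 1)) nb[k++] = lab(r - 1, c + 1);
      if (c > 0 && mask(r, c - 1)) nb[k++] = lab(r, c - 1);
      if (k == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        int m = nb[0];
        for (int i = 1; i < k; ++i) m = std::min(m, nb[i]);
        lab(r, c) = m;
        for (int i = 0; i < k; ++i) uf_union(parent, m, nb[i]);
      }
    }
  }
  // flatten and relabel consecutively in raster order
  std::vector<int> remap(parent.size(), 0);
  int out_next = 1;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      int root = uf_find(parent, lab(r, c));
      if (remap[root] == 0) remap[root] = out_next++;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}
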